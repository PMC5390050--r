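#' Consensus statistics of laboratory means
#'
#' Arithmetic mean, sample standard deviation (n - 1) and %RSD of a set of
#' per-laboratory results. With a data frame input, existing dplyr groups
#' (or a `material`/`class` structure built by the caller) are respected,
#' giving one consensus row per group.
#'
#' @param data A numeric vector of lab means, or a data frame containing
#'   `value` (optionally grouped).
#' @param value Column holding lab results when `data` is a data frame.
#' @return A tibble with columns `n`, `mean`, `sd`, `rsd_percent` (plus any
#'   grouping columns).
#' @export
#' @examples
#' consensus_stats(c(337.3, 344.2, 323.8, 332.0, 323.2, 306.2, 312.0))
consensus_stats <- function(data, value = "value") {
  if (is.numeric(data)) {
    return(consensus_one(data))
  }
  check_columns(data, value, "interlab table")
  data |>
    dplyr::summarise(consensus_one(.data[[value]]), .groups = "drop")
}

consensus_one <- function(x) {
  if (length(x) < 2 || anyNA(x)) {
    abort("consensus statistics need >= 2 non-NA lab values.")
  }
  m <- mean(x)
  s <- sd(x)
  tibble::tibble(n = length(x), mean = m, sd = s, rsd_percent = 100 * s / m)
}

classify_z <- function(z) {
  dplyr::case_when(
    abs(z) <= 2 ~ "satisfactory",
    abs(z) < 3 ~ "doubtful",
    TRUE ~ "unsatisfactory"
  )
}

#' Proficiency z-scores
#'
#' For each value set (one analyte in one material), computes
#' `z = (x - mu) / sigma` with `mu` the mean and `sigma` the sample SD
#' (n - 1) of the participating labs' results — the same convention as
#' [consensus_stats()]. Classification: |z| <= 2 satisfactory,
#' 2 < |z| < 3 doubtful, |z| >= 3 unsatisfactory. A robust variant
#' (median / MAD) is available but off by default.
#'
#' @param data A data frame with columns `lab` and `value`; existing dplyr
#'   groups define the value sets (e.g. group by material and analyte).
#' @param robust Use median and MAD instead of mean and sample SD.
#' @return The input plus columns `z` and `classification`.
#' @export
#' @examples
#' d <- data.frame(lab = 1:7, value = c(337.3, 344.2, 323.8, 332.0, 323.2, 306.2, 312.0))
#' z_scores(d)
z_scores <- function(data, robust = FALSE) {
  check_columns(data, c("lab", "value"), "interlab table")
  data |>
    dplyr::mutate(z = z_one(.data$value, robust = robust),
                  classification = classify_z(.data$z)) |>
    dplyr::ungroup()
}

z_one <- function(x, robust = FALSE) {
  if (length(x) < 2) abort("z-scores need >= 2 lab results.")
  if (length(x) < 3) {
    warn("z-scores from only 2 labs: the consensus SD is uninformative.")
  }
  center <- if (robust) median(x) else mean(x)
  scale <- if (robust) stats::mad(x) else sd(x)
  if (scale == 0) abort("z-scores undefined: zero dispersion across labs.")
  (x - center) / scale
}

#' Per-laboratory z-score summary
#'
#' Average, median, minimum and maximum z-score per laboratory across
#' analytes/materials, the descriptors used to judge whether between-lab
#' bias dominates within-lab variation.
#'
#' @param data Output of [z_scores()] (columns `lab`, `z`).
#' @return A tibble per lab: `avg_z`, `med_z`, `min_z`, `max_z`, `n`.
#' @export
z_score_summary <- function(data) {
  check_columns(data, c("lab", "z"), "z-score table")
  data |>
    dplyr::group_by(.data$lab) |>
    dplyr::summarise(
      avg_z = mean(.data$z),
      med_z = median(.data$z),
      min_z = min(.data$z),
      max_z = max(.data$z),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Control-sample quality gate
#'
#' Screens laboratories on their control-sample result before consensus and
#' z-score evaluation. The default policy scores each lab against the
#' consensus of the *other* labs (leave-one-out z) and excludes labs with
#' |z| above the cutoff; the deleted z is used because a gross outlier
#' inflates the plain consensus SD enough to mask itself in a small lab
#' set. The plain-consensus variant is available as `policy = "z"`.
#' Exclusion runs for a single round: the consensus is recomputed once on
#' the retained labs.
#'
#' @param data A data frame with columns `lab` and `value` (one control
#'   result per lab).
#' @param z_max Exclusion cutoff on |z| (default 3).
#' @param policy `"loo_z"` (leave-one-out, default) or `"z"` (plain
#'   consensus z).
#' @return An object of class `qc_gate`: a list with `labs` (tibble: `lab`,
#'   `value`, `z`, `excluded`), `included`/`excluded` (lab ids), and
#'   `consensus` (retained-lab consensus statistics).
#' @export
qc_gate <- function(data, z_max = 3, policy = c("loo_z", "z")) {
  policy <- match.arg(policy)
  check_columns(data, c("lab", "value"), "control table")
  if (anyNA(data$value)) abort("control values contain NA.")
  if (dplyr::n_distinct(data$lab) != nrow(data)) {
    abort("one control result per lab is required (duplicate lab ids).")
  }
  if (nrow(data) < 3) abort("the QC gate needs >= 3 labs.")
  check_number(z_max, "z_max", min = 0, strict_min = TRUE)

  x <- data$value
  z <- if (policy == "z") {
    z_one(x)
  } else {
    vapply(seq_along(x), function(i) {
      rest <- x[-i]
      s <- sd(rest)
      if (s == 0) {
        if (x[i] == rest[1]) 0 else Inf
      } else {
        (x[i] - mean(rest)) / s
      }
    }, numeric(1))
  }
  excluded <- abs(z) > z_max
  if (all(excluded)) abort("QC gate excluded every laboratory.")
  if (any(excluded)) {
    rlang::inform(sprintf(
      "QC gate (policy %s, |z| > %g): excluding lab(s) %s", policy, z_max,
      paste(data$lab[excluded], collapse = ", ")))
  }
  structure(
    list(
      labs = tibble::tibble(lab = data$lab, value = x, z = z,
                            excluded = excluded),
      included = data$lab[!excluded],
      excluded = data$lab[excluded],
      consensus = consensus_one(x[!excluded])
    ),
    class = "qc_gate"
  )
}

#' @export
print.qc_gate <- function(x, ...) {
  cat(sprintf("<qc_gate> %d lab(s) retained, %d excluded%s\n",
              length(x$included), length(x$excluded),
              if (length(x$excluded) > 0) {
                paste0(" (", paste(x$excluded, collapse = ", "), ")")
              } else ""))
  cat(sprintf("  retained consensus: mean %.4g, sd %.3g, RSD %.2f%%\n",
              x$consensus$mean, x$consensus$sd, x$consensus$rsd_percent))
  invisible(x)
}

#' Within-laboratory precision summary
#'
#' %RSD per laboratory (and per material/analyte grouping, if those columns
#' exist) across that lab's independent measurements.
#'
#' @param data A data frame with columns `lab` and `value`; optional
#'   `material` and `analyte` columns extend the grouping.
#' @return A tibble per group: `n`, `mean`, `rsd_percent`.
#' @export
within_lab_precision_summary <- function(data) {
  check_columns(data, c("lab", "value"), "interlab table")
  by <- intersect(c("lab", "material", "analyte"), names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      rsd_percent = 100 * sd(.data$value) / mean(.data$value),
      .groups = "drop"
    )
}
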