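#' Amplification efficiency from a standard-curve slope
#'
#' A dilution series gives a Cq-vs-log10(template) regression; its slope
#' determines the fold-amplification per cycle, `E = 10^(-1/slope)`. A
#' perfect doubling corresponds to a slope of -3.3219 (E = 2).
#'
#' @param slope slope of Cq against log10 dilution; must be negative.
#' @return efficiency E (fold per cycle); values outside [1.5, 2.1] are
#'   flagged with a warning.
#' @export
efficiency_from_slope <- function(slope) {
  if (any(slope >= 0)) stop("standard-curve slope must be negative")
  E <- 10^(-1 / slope)
  out <- E < 1.5 | E > 2.1
  if (any(out))
    warning("efficiency out of the plausible [1.5, 2.1] range: ",
            paste(signif(E[out], 4), collapse = ", "))
  E
}

normalize_efficiencies <- function(efficiencies, targets) {
  miss <- setdiff(targets, names(efficiencies))
  if (length(miss))
    stop("no efficiency for target(s): ", paste(miss, collapse = ", "))
  E <- efficiencies[targets]
  pct <- E > 2.5 # percent-efficiency inputs, e.g. 95 meaning E = 1.95
  if (any(pct)) {
    warning("efficiencies ", paste(names(E)[pct], collapse = ", "),
            " look like percentages; converted via E = 1 + pct/100")
    E[pct] <- 1 + E[pct] / 100
  }
  warn <- E < 1.5 | E > 2.1
  if (any(warn))
    warning("efficiency outside [1.5, 2.1] for ",
            paste(names(E)[warn], collapse = ", "))
  E
}

#' Efficiency-corrected relative expression from Cq values
#'
#' Relative quantification in the efficiency-corrected form: with
#' replicate-mean quantification cycles, the expression of target t in
#' sample s relative to the calibrator sample is
#' `ratio = E_t^(Cq_t,cal - Cq_t,s) / E_ref^(Cq_ref,cal - Cq_ref,s)`,
#' normalised by a housekeeping reference target. When every efficiency is
#' exactly 2, this reduces to the classical `2^(-ddCq)`. The plain
#' `2^(-ddCq)` form is also available via `method = "ddcq"`.
#'
#' @param cq data.frame with columns `sample_id`, `target_id`, `replicate`,
#'   `cq`.
#' @param efficiencies named numeric vector of per-target fold-per-cycle
#'   efficiencies in [1, 2] (percent inputs are auto-converted with a
#'   warning).
#' @param reference housekeeping target id (the gapC role).
#' @param calibrator calibrator sample id; its own ratio is 1 for every
#'   target.
#' @param method `"pfaffl"` (efficiency-corrected, default) or `"ddcq"`
#'   (assumes perfect doubling for every target).
#' @return data.frame of class addition `ExpressionRatio`: `sample_id`,
#'   `target_id`, `ratio`, `log2_ratio`, `ratio_lo`, `ratio_hi` (replicate
#'   range propagated through the ratio). Samples lacking reference
#'   measurements are skipped with a warning.
#' @export
relative_expression <- function(cq, efficiencies, reference, calibrator,
                                method = c("pfaffl", "ddcq")) {
  method <- match.arg(method)
  need <- c("sample_id", "target_id", "replicate", "cq")
  if (!all(need %in% names(cq)))
    stop("Cq table needs columns: ", paste(need, collapse = ", "))
  if (!reference %in% cq$target_id)
    stop("reference target ", reference, " absent from Cq table")
  if (!calibrator %in% cq$sample_id)
    stop("calibrator sample ", calibrator, " absent from Cq table")
  targets <- unique(cq$target_id)
  E <- if (method == "pfaffl") normalize_efficiencies(efficiencies, targets)
       else setNames(rep(2, length(targets)), targets)
  mean_cq <- stats::aggregate(cq ~ sample_id + target_id, cq, mean)
  rng_cq <- stats::aggregate(cq ~ sample_id + target_id, cq,
                             function(x) diff(range(x)) / 2)
  get_cq <- function(tab, s, t) {
    v <- tab$cq[tab$sample_id == s & tab$target_id == t]
    if (length(v)) v else NA_real_
  }
  samples <- unique(cq$sample_id)
  out <- list()
  for (s in samples) {
    ref_s <- get_cq(mean_cq, s, reference)
    ref_cal <- get_cq(mean_cq, calibrator, reference)
    if (is.na(ref_s)) {
      warning("sample ", s, " has no reference measurements; skipped")
      next
    }
    for (t in setdiff(targets, reference)) {
      t_s <- get_cq(mean_cq, s, t)
      t_cal <- get_cq(mean_cq, calibrator, t)
      if (is.na(t_s) || is.na(t_cal)) next
      ratio <- E[[t]]^(t_cal - t_s) / E[[reference]]^(ref_cal - ref_s)
      half <- get_cq(rng_cq, s, t)
      out[[length(out) + 1]] <- data.frame(
        sample_id = s, target_id = t, ratio = ratio,
        log2_ratio = log2(ratio),
        ratio_lo = ratio / E[[t]]^half, ratio_hi = ratio * E[[t]]^half,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  class(out) <- c("ExpressionRatio", class(out))
  out
}

#' Read a Cq table TSV
#' @param path TSV with columns `sample_id`, `target_id`, `replicate`, `cq`.
#' @return data.frame for [relative_expression].
#' @export
read_cq_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "target_id", "replicate", "cq")
  if (!all(need %in% names(tab)))
    stop("Cq TSV needs columns: ", paste(need, collapse = ", "))
  tab[need]
}

#' Read per-target efficiencies from TSV
#'
#' Accepts either a column `E` (fold per cycle) or `slope` (standard-curve
#' slope, converted via [efficiency_from_slope]).
#'
#' @param path TSV with columns `target_id` and `E` or `slope`.
#' @return named numeric vector of efficiencies.
#' @export
read_efficiency_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!"target_id" %in% names(tab))
    stop("efficiency TSV needs a target_id column")
  if (!is.null(tab$E)) setNames(tab$E, tab$target_id)
  else if (!is.null(tab$slope))
    setNames(efficiency_from_slope(tab$slope), tab$target_id)
  else stop("efficiency TSV needs an E or slope column")
}
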