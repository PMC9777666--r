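#' Taste activity value
#'
#' TAV is the ratio of a compound's concentration to its taste detection
#' threshold; TAV > 1 marks the compound as taste-active in the matrix.
#'
#' @param content concentration in mg/100 g (vectorised, must be >= 0).
#' @param threshold taste threshold in mg/100 g (> 0, recycled).
#' @return dimensionless ratio `content / threshold`.
#' @examples
#' tav(673.59, 50)  # arginine in abdomen meat, 13.47
#' @export
tav <- function(content, threshold) {
  if (any(threshold <= 0)) stop("taste threshold must be > 0")
  if (any(content < 0)) stop("concentration must be >= 0")
  content / threshold
}

#' Equivalent umami concentration with nucleotide synergy
#'
#' The MSG-equivalent umami intensity of a mixture of umami amino acids
#' (Glu, Asp) and 5'-nucleotides (IMP, GMP, AMP):
#' \deqn{EUC = \sum_i a_i b_i + 1218 \left(\sum_i a_i b_i\right)
#'   \left(\sum_j a_j b_j\right)}
#' where the \eqn{a} are concentrations in g/100 g, \eqn{b_i} are relative
#' umami concentrations of the amino acids to MSG (Glu 1, Asp 0.077),
#' \eqn{b_j} those of the nucleotides to IMP (IMP 1, GMP 2.3, AMP 0.18),
#' and 1218 is the synergy constant. Inputs are taken in mg/100 g (the unit
#' of the compound table) and converted internally. Below-detection
#' nucleotides enter as 0 and the bilinear synergy term then vanishes.
#'
#' @param glu,asp,imp,gmp,amp concentrations in mg/100 g (vectorised).
#' @param coefficients optional replacement for [umami_coefficients()].
#' @return numeric vector of EUC in g MSG/100 g.
#' @examples
#' euc(glu = 66.12, asp = 7.12, imp = 81.39, gmp = 2.97, amp = 123.63)
#' @export
euc <- function(glu, asp, imp, gmp, amp,
                coefficients = umami_coefficients()) {
  if (any(c(glu, asp, imp, gmp, amp) < 0))
    stop("EUC inputs must be >= 0")
  comps <- euc_terms(glu, asp, imp, gmp, amp, coefficients)
  comps$umami_term + comps$synergy_term
}

#' @rdname euc
#' @return `euc_terms()` returns a data frame with the additive
#'   `umami_term` (g/100 g), the `synergy_term` (g MSG/100 g) and their sum
#'   `euc`.
#' @export
euc_terms <- function(glu, asp, imp, gmp, amp,
                      coefficients = umami_coefficients()) {
  b <- coefficients
  u <- (glu * b$b_faa[["Glu"]] + asp * b$b_faa[["Asp"]]) / 1000
  nuc <- (imp * b$b_nuc[["IMP"]] + gmp * b$b_nuc[["GMP"]] +
            amp * b$b_nuc[["AMP"]]) / 1000
  data.frame(umami_term = u,
             synergy_term = b$synergy_constant * u * nuc,
             euc = u + b$synergy_constant * u * nuc)
}

#' @rdname euc
#' @return `umami_coefficients()` returns the default relative umami
#'   concentrations and synergy constant as a list with elements `b_faa`,
#'   `b_nuc`, `synergy_constant`.
#' @export
umami_coefficients <- function() {
  list(b_faa = c(Glu = 1, Asp = 0.077),
       b_nuc = c(IMP = 1, GMP = 2.3, AMP = 0.18),
       synergy_constant = 1218)
}

#' Per-sample EUC from a compound summary
#'
#' Evaluates [euc()] at the per-sample mean concentrations of Glu, Asp,
#' IMP, GMP and AMP. Note that when the published EUC is a mean of
#' per-replicate EUC values, evaluating the nonlinear formula at the means
#' deviates slightly (about 0.5% at the study's coefficients of variation).
#'
#' @param summary a [sample_summary()] covering the five EUC compounds.
#' @return data frame with columns `sample`, `umami_term`, `synergy_term`,
#'   `euc` (g MSG/100 g).
#' @examples
#' euc_table(load_crab_compounds())
#' @export
euc_table <- function(summary) {
  stopifnot(inherits(summary, "sample_summary"))
  samples <- intersect(crab_samples(), unique(summary$sample))
  pick <- function(s, cp) {
    v <- summary$mean[summary$sample == s & summary$compound == cp]
    if (!length(v)) stop("summary lacks ", cp, " for ", s)
    v
  }
  rows <- lapply(samples, function(s)
    cbind(sample = s,
          euc_terms(pick(s, "Glu"), pick(s, "Asp"), pick(s, "IMP"),
                    pick(s, "GMP"), pick(s, "AMP"))))
  do.call(rbind, rows)
}

#' Taste threshold registry
#'
#' Thresholds are matrix- and panel-dependent; the packaged registry
#' anchors arginine at 50 mg/100 g (the value consistent with the study's
#' reported Arg TAV range of 12.89-13.47) and carries literature
#' placeholder values for the remaining compounds, which users are expected
#' to replace for their own matrices via `read_thresholds()`.
#'
#' @param path CSV with columns `compound`, `threshold_mg_per_100g` and
#'   optionally `source`.
#' @return data frame of class `"threshold_registry"` with columns
#'   `compound`, `threshold`, `source`.
#' @export
read_thresholds <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("compound", "threshold_mg_per_100g") %in% names(df)))
    stop("threshold CSV needs columns compound, threshold_mg_per_100g")
  out <- data.frame(compound = df$compound,
                    threshold = as.numeric(df$threshold_mg_per_100g),
                    source = if (is.null(df$source)) "" else df$source,
                    stringsAsFactors = FALSE)
  if (anyNA(out$threshold) || any(out$threshold <= 0))
    stop("thresholds must be positive numbers")
  structure(out, class = c("threshold_registry", "data.frame"))
}

#' @rdname read_thresholds
#' @export
default_thresholds <- function() {
  read_thresholds(system.file("extdata", "thresholds.csv",
                              package = "umamipanel", mustWork = TRUE))
}

#' TAV of every covered compound in every sample
#'
#' Compounds absent from the registry are skipped with a message (cystine
#' has no agreed threshold, for example).
#'
#' @param summary a [sample_summary()].
#' @param registry a [read_thresholds()] registry;
#'   [default_thresholds()] by default.
#' @return data frame with columns `sample`, `compound`, `tav` and
#'   `active` (`tav > 1`).
#' @export
tav_table <- function(summary, registry = default_thresholds()) {
  stopifnot(inherits(summary, "sample_summary"))
  covered <- summary$compound %in% registry$compound
  skipped <- setdiff(unique(summary$compound[!covered]), character())
  if (length(skipped))
    message("no threshold for: ", paste(skipped, collapse = ", "),
            " (skipped)")
  sub <- summary[covered, , drop = FALSE]
  thr <- registry$threshold[match(sub$compound, registry$compound)]
  out <- data.frame(sample = sub$sample, compound = sub$compound,
                    tav = tav(sub$mean, thr), stringsAsFactors = FALSE)
  out$active <- out$tav > 1
  rownames(out) <- NULL
  out
}

#' Relative difference in percent of a reference quantity
#'
#' `pct_more(a, b)` returns `(a - b) / a * 100`: how much more of a
#' constituent the reference sample `a` holds, expressed as a percentage of
#' the *reference* (first) argument. Note this deviates from the everyday
#' reading of "X% more than b", which would divide by `b`; the
#' reference-denominator convention is the one under which the package's
#' worked contrasts reproduce the study's printed percentages.
#'
#' @param a reference quantity (> 0).
#' @param b compared quantity.
#' @return percent difference relative to `a`.
#' @examples
#' pct_more(98.77, 69.22)  # 29.92
#' @export
pct_more <- function(a, b) {
  if (any(a <= 0)) stop("reference quantity must be > 0")
  (a - b) / a * 100
}

#' Share of a part in a total, in percent
#'
#' @param part,total quantities with `0 <= part <= total`, `total > 0`.
#' @return `part / total * 100`.
#' @examples
#' share_of_total(422.25, 1347.76)  # 31.33
#' @export
share_of_total <- function(part, total) {
  if (any(total <= 0)) stop("total must be > 0")
  if (any(part < 0 | part > total)) stop("part must lie in [0, total]")
  part / total * 100
}
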