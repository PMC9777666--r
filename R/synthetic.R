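#' Synthetic replicate-level compound data
#'
#' Draws per-replicate concentrations from truncated normal distributions
#' (lower bound 0) with the per-cell means and SDs of a [sample_summary()]
#' — by default the packaged crab compound summary, whose published
#' moments the generated replicates then emulate. Truncation guards the
#' high-CV cells (gonad potassium, for instance) against negative draws.
#' Cells flagged as not detected generate zeros.
#'
#' @param summary a [sample_summary()] supplying per-cell mean and sd.
#' @param n replicates per cell (default 3, the study's replication).
#' @param seed integer seed; equal seeds give byte-identical tables.
#' @return a [compound_table()] with `n` replicates per (sample, compound).
#' @examples
#' tab <- gen_compound_replicates(n = 3, seed = 42)
#' summarize_replicates(tab)[1:3, ]
#' @export
gen_compound_replicates <- function(summary = load_crab_compounds(),
                                    n = 3, seed = 1) {
  stopifnot(inherits(summary, "sample_summary"))
  .with_seed(seed, {
    recs <- lapply(seq_len(nrow(summary)), function(i) {
      m <- summary$mean[i]
      s <- summary$sd[i]
      det <- summary$detected[i]
      v <- if (!det || s == 0) rep(m, n)
           else stats::qnorm(stats::runif(n, stats::pnorm(0, m, s), 1), m, s)
      data.frame(sample = summary$sample[i], replicate = seq_len(n),
                 compound = summary$compound[i], value = v,
                 detected = det, stringsAsFactors = FALSE)
    })
    compound_table(do.call(rbind, recs))
  })
}

#' Specification of a synthetic consumer panel
#'
#' Defaults reproduce the study conditions: 93 consumers, the nine crab
#' samples, emoji selection probabilities equal to the published selection
#' frequencies, and 9-point hedonic scores drawn around per-sample means
#' spread over the published preference range 4.69-6.30 — the
#' hepatopancreas of the Chongming crab at the minimum (the only sample
#' below 5), abdomen meat most liked, gonads intermediate.
#'
#' @param n_consumers panel size (default 93).
#' @param samples sample codes (default the nine-sample design).
#' @param emoji_prob emoji x sample matrix of selection probabilities in
#'   \[0, 1\]; default the published frequencies / 100 (all 23 emojis, so
#'   the two never-selected emojis have probability 0).
#' @param hedonic_mean named per-sample means on the 9-point scale.
#' @param hedonic_sd common SD of the latent normal scores (default 1.3).
#' @return list of class `"panel_spec"`.
#' @export
panel_spec <- function(n_consumers = 93, samples = crab_samples(),
                       emoji_prob = NULL,
                       hedonic_mean = c("M-C-JH" = 6.30, "M-T-JH" = 5.90,
                                        "M-T-CJ" = 6.15, "H-C-JH" = 4.69,
                                        "H-T-JH" = 5.15, "H-T-CJ" = 5.30,
                                        "G-C-JH" = 5.40, "G-T-JH" = 5.80,
                                        "G-T-CJ" = 5.60),
                       hedonic_sd = 1.3) {
  if (is.null(emoji_prob)) {
    freq <- load_emoji_frequencies(drop_zero = FALSE)
    emoji_prob <- unclass(freq)[, samples, drop = FALSE] / 100
  }
  if (any(emoji_prob < 0 | emoji_prob > 1))
    stop("emoji probabilities must lie in [0, 1]")
  hedonic_mean <- hedonic_mean[samples]
  if (anyNA(hedonic_mean) || any(hedonic_mean < 1 | hedonic_mean > 9))
    stop("hedonic means must cover every sample and lie in [1, 9]")
  if (n_consumers < 1) stop("need at least one consumer")
  structure(list(n_consumers = as.integer(n_consumers), samples = samples,
                 emoji_prob = emoji_prob, hedonic_mean = hedonic_mean,
                 hedonic_sd = hedonic_sd),
            class = "panel_spec")
}

#' Synthetic CATA responses
#'
#' Independent Bernoulli draws per (consumer, sample, emoji) at the
#' probabilities in the panel spec. Marginal selection frequencies converge
#' to the spec probabilities; co-selection structure between emojis is
#' deliberately not modeled (the published data give marginal frequencies
#' only).
#'
#' @param spec a [panel_spec()].
#' @param seed integer seed.
#' @return binary array indexed (consumer, sample, emoji) with dimnames.
#' @export
gen_cata <- function(spec = panel_spec(), seed = 1) {
  stopifnot(inherits(spec, "panel_spec"))
  p <- spec$emoji_prob
  .with_seed(seed, {
    arr <- array(0L, dim = c(spec$n_consumers, length(spec$samples),
                             nrow(p)),
                 dimnames = list(NULL, spec$samples, rownames(p)))
    for (e in seq_len(nrow(p))) for (s in seq_along(spec$samples))
      arr[, s, e] <- stats::rbinom(spec$n_consumers, 1L,
                                   p[e, spec$samples[s]])
    arr
  })
}

#' Synthetic 9-point hedonic scores
#'
#' Normal draws at the per-sample means, rounded to integers and clipped to
#' the 1-9 scale; extreme scores are correspondingly rare, matching the
#' roughly normal preference distributions the panel reported.
#'
#' @inheritParams gen_cata
#' @return integer matrix, consumers x samples, values in 1..9.
#' @export
gen_hedonic <- function(spec = panel_spec(), seed = 1) {
  stopifnot(inherits(spec, "panel_spec"))
  .with_seed(seed, {
    m <- sapply(spec$samples, function(s)
      pmin(9L, pmax(1L, as.integer(round(
        stats::rnorm(spec$n_consumers, spec$hedonic_mean[[s]],
                     spec$hedonic_sd))))))
    rownames(m) <- NULL
    m
  })
}

#' Synthetic preference dataset with planted compound-preference link
#'
#' Generates replicate-level values of the six preference-relevant
#' compounds (Arg, Ala, Gly, Pro, K, Ca) via [gen_compound_replicates()]
#' and plants a known monotone relation from the min-max-normalized inputs
#' to a preference score on the 9-point scale:
#' \describe{
#'   \item{`"linear"`}{score index = weighted sum of the normalized
#'     inputs.}
#'   \item{`"saturating"`}{each normalized input first passes through a
#'     tanh saturation centered at a compound-specific half-saturation
#'     point (taste intensity saturates with concentration, and each
#'     compound saturates at its own characteristic level), so the planted
#'     map is a sum of six axis-aligned sigmoidal ramps firing at different
#'     points of the concentration range — representable by a few hidden
#'     units but not by one.}
#' }
#' The index is rescaled to \[1, 9\] and Gaussian noise (sd `noise_sd` on
#' the normalized scale, times the 8-point range) is added. The returned
#' ground-truth weights support recovery assertions: with `noise_sd = 0`
#' and a linear link, `y` is an exact affine function of `X %*% weights`.
#'
#' @param n_rows number of observations (default 200).
#' @param weights named weights over the six inputs (at least one nonzero).
#' @param link `"linear"` or `"saturating"`.
#' @param noise_sd noise SD on the normalized (0-1) preference scale.
#' @param seed integer seed.
#' @param summary compound summary the replicates are drawn from.
#' @return list with `X` (n_rows x 6 matrix, mg/100 g), `y` (preference,
#'   1-9 scale), `weights`, `link`, `noise_sd`.
#' @export
gen_preference_dataset <- function(n_rows = 200,
                                   weights = c(Arg = 0.30, Ala = 0.20,
                                               Gly = 0.15, Pro = 0.10,
                                               K = 0.15, Ca = 0.10),
                                   link = c("linear", "saturating"),
                                   noise_sd = 0.05, seed = 1,
                                   summary = load_crab_compounds()) {
  link <- match.arg(link)
  if (all(weights == 0)) stop("at least one weight must be nonzero")
  if (noise_sd < 0) stop("noise sd must be >= 0")
  inputs <- names(weights)
  sub <- summary[summary$compound %in% inputs, , drop = FALSE]
  n_rep <- ceiling(n_rows / length(unique(sub$sample)))
  tab <- gen_compound_replicates(sub, n = n_rep, seed = seed)
  wide <- stats::reshape(as.data.frame(tab)[c("sample", "replicate",
                                              "compound", "value")],
                         idvar = c("sample", "replicate"),
                         timevar = "compound", direction = "wide")
  X <- as.matrix(wide[paste0("value.", inputs)])
  colnames(X) <- inputs
  X <- X[seq_len(n_rows), , drop = FALSE]
  Xn <- scale_minmax(X, fit_scaler(X))
  Z <- if (link == "saturating") {
    centers <- c(Arg = 0.3, Ala = 0.5, Gly = 0.7, Pro = 0.4,
                 K = 0.6, Ca = 0.5)[inputs]
    centers[is.na(centers)] <- 0.5
    tanh(6 * sweep(Xn, 2, centers))
  } else Xn
  s <- as.vector(Z %*% weights)
  sn <- (s - min(s)) / (max(s) - min(s))
  eps <- .with_seed(seed + 7L, stats::rnorm(n_rows, 0, noise_sd))
  list(X = X, y = 1 + 8 * (sn + eps), weights = weights, link = link,
       noise_sd = noise_sd)
}
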