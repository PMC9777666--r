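#' Emoji lexicon of the CATA ballot
#'
#' The check-all-that-apply ballot offered 23 facial emojis: 13 positive,
#' 8 negative and 2 neutral. Emojis are keyed by a slug of their definition
#' (e.g. `"grinning"` for "Grinning face").
#'
#' @return data frame with columns `emoji`, `label`, `valence`.
#' @examples
#' table(emoji_lexicon()$valence)
#' @export
emoji_lexicon <- function() {
  df <- .load_emoji_table()
  df[c("emoji", "label", "valence")]
}

.load_emoji_table <- function() {
  path <- system.file("extdata", "emoji_frequencies.csv",
                      package = "umamipanel", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Packaged emoji x sample selection frequencies
#'
#' Percent of the 93 consumers selecting each emoji for each sample, as
#' published. Two emojis (stuck-out tongue with winking eyes, crying face)
#' were never selected and appear as all-zero rows.
#'
#' @param drop_zero drop all-zero emoji rows (required before
#'   correspondence analysis); default `TRUE`.
#' @return a [contingency_table()] on the percent basis, with the
#'   published Cochran-test p-values attached as attribute `"p_printed"`.
#' @export
load_emoji_frequencies <- function(drop_zero = TRUE) {
  df <- .load_emoji_table()
  m <- as.matrix(df[crab_samples()])
  rownames(m) <- df$emoji
  p <- stats::setNames(df$p_printed, df$emoji)
  if (drop_zero) {
    keep <- rowSums(m) > 0
    m <- m[keep, , drop = FALSE]
    p <- p[keep]
  }
  out <- contingency_table(m, basis = "percent")
  attr(out, "p_printed") <- p
  out
}

#' Emoji x sample contingency table
#'
#' @param counts non-negative numeric matrix, emojis (or any descriptors)
#'   in rows, samples in columns.
#' @param basis `"count"` or `"percent"` (entries <= 100).
#' @return the matrix with class `"contingency_table"` and attribute
#'   `"basis"`.
#' @export
contingency_table <- function(counts, basis = c("count", "percent")) {
  basis <- match.arg(basis)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("contingency entries must be >= 0")
  if (basis == "percent" && any(counts > 100))
    stop("percent-basis entries must be <= 100")
  structure(counts, basis = basis,
            class = c("contingency_table", class(counts)))
}

#' Emoji selection frequencies from raw CATA responses
#'
#' @param responses binary array indexed (consumer, sample, emoji), as
#'   produced by [gen_cata()]; every consumer rates every sample
#'   (complete block design).
#' @param basis `"percent"` (default): 100 x selections / consumers;
#'   or `"count"`.
#' @return a [contingency_table()], emojis in rows, samples in columns.
#' @export
frequency_table <- function(responses, basis = c("percent", "count")) {
  basis <- match.arg(basis)
  if (length(dim(responses)) != 3L || !length(responses))
    stop("responses must be a nonempty consumer x sample x emoji array")
  if (!all(responses %in% c(0, 1))) stop("responses must be binary")
  m <- if (basis == "percent") apply(responses, c(3, 2), mean) * 100
       else apply(responses, c(3, 2), sum)
  contingency_table(m, basis)
}

#' Cochran's Q test for equal selection proportions across samples
#'
#' For n consumers (rows) by k samples (columns) of binary selections in a
#' complete block design,
#' \deqn{Q = (k-1)\,\frac{k \sum_j C_j^2 - (\sum_j C_j)^2}
#'   {k \sum_i R_i - \sum_i R_i^2}}
#' with column totals \eqn{C_j} and row totals \eqn{R_i}; rows that select
#' everything or nothing carry no information and cancel from the
#' statistic. The default p-value is asymptotic, chi-squared with k - 1
#' degrees of freedom; `method = "exact"` instead enumerates every
#' within-row rearrangement of the selections (the permutation null of the
#' complete block design) and reports the tail probability
#' \eqn{P(Q^{perm} \ge Q)}, which is preferable for very small panels where
#' the chi-square approximation is coarse. A degenerate denominator (all
#' rows uninformative) yields Q = 0, p = 1.
#'
#' @param selections binary matrix, consumers x samples.
#' @param method `"asymptotic"` (default) or `"exact"` (exhaustive
#'   within-row permutation; only feasible for small tables — the
#'   enumeration is capped at 10^6 arrangements).
#' @return an object of class `"htest"`.
#' @export
cochran_q <- function(selections, method = c("asymptotic", "exact")) {
  method <- match.arg(method)
  m <- as.matrix(selections)
  if (!all(m %in% c(0, 1))) stop("selections must be binary 0/1")
  k <- ncol(m)
  if (k < 2) stop("need at least two samples (columns)")
  Cj <- colSums(m)
  Ri <- rowSums(m)
  den <- k * sum(Ri) - sum(Ri^2)
  Q <- if (den == 0) 0 else (k - 1) * (k * sum(Cj^2) - sum(Cj)^2) / den
  p <- if (den == 0) 1
       else if (method == "asymptotic")
         stats::pchisq(Q, df = k - 1, lower.tail = FALSE)
       else .cochran_exact_p(m, Q)
  structure(list(statistic = c(Q = Q), parameter = c(df = k - 1),
                 p.value = p,
                 method = paste0("Cochran's Q test (", method, ")"),
                 data.name = deparse(substitute(selections))),
            class = "htest")
}

# Exhaustive permutation null of Cochran's Q: each row's selections are
# rearranged over the k samples; distinct arrangements of a row with R_i
# ones number choose(k, R_i) and are equiprobable. Row sums are invariant,
# so only the column sums need tracking.
.cochran_exact_p <- function(m, q_obs) {
  k <- ncol(m)
  Ri <- rowSums(m)
  den <- k * sum(Ri) - sum(Ri^2)
  arr <- lapply(Ri, function(r) {
    ones <- utils::combn(k, r)
    lapply(seq_len(ncol(ones)), function(j) {
      v <- numeric(k); v[ones[, j]] <- 1; v
    })
  })
  if (prod(vapply(arr, length, 1)) > 1e6)
    stop("exact enumeration infeasible: more than 1e6 arrangements")
  colsums <- Reduce(function(acc, row_arr) {
    out <- lapply(acc, function(cs) lapply(row_arr, function(v) cs + v))
    unlist(out, recursive = FALSE)
  }, arr, accumulate = FALSE, init = list(numeric(k)))
  qs <- vapply(colsums, function(Cj)
    (k - 1) * (k * sum(Cj^2) - sum(Cj)^2) / den, 1)
  mean(qs >= q_obs - 1e-12)
}

# Exact-binomial or chi-square McNemar p-value on discordant counts b, c.
# Exact below `exact_max` discordant pairs, continuity-uncorrected
# chi-square approximation above (standard sensometrics practice).
.mcnemar_p <- function(b, c, exact_max = 25) {
  n <- b + c
  if (n == 0) return(1)
  if (n < exact_max) min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
  else stats::pchisq((b - c)^2 / n, df = 1, lower.tail = FALSE)
}

#' Pairwise McNemar tests with Bonferroni correction
#'
#' Runs all k(k-1)/2 paired McNemar comparisons between sample columns,
#' each at level `alpha / (k(k-1)/2)` (Bonferroni), and summarises the
#' result as a compact letter display: samples sharing a letter are not
#' significantly different. The exact binomial form of the test is used
#' when the discordant count is below 25, the continuity-uncorrected
#' chi-square approximation otherwise. Letters are assigned by
#' insert-and-absorb over the significance graph, with ties broken by
#' column order.
#'
#' @param selections binary matrix, consumers x samples (k >= 2).
#' @param alpha family-wise significance level (default 0.05).
#' @return list of class `"mcnemar_pairwise"` with elements `comparisons`
#'   (data frame: pair, discordant counts, p, Bonferroni-adjusted
#'   significance), `letters` (named character vector per sample),
#'   `alpha` and `alpha_per_test`.
#' @export
mcnemar_pairwise <- function(selections, alpha = 0.05) {
  m <- as.matrix(selections)
  if (!all(m %in% c(0, 1))) stop("selections must be binary 0/1")
  k <- ncol(m)
  if (k < 2) stop("need at least two samples")
  if (is.null(colnames(m))) colnames(m) <- paste0("S", seq_len(k))
  pairs <- utils::combn(k, 2)
  ntest <- ncol(pairs)
  comp <- do.call(rbind, lapply(seq_len(ntest), function(t) {
    i <- pairs[1, t]; j <- pairs[2, t]
    b <- sum(m[, i] == 1 & m[, j] == 0)
    c_ <- sum(m[, i] == 0 & m[, j] == 1)
    data.frame(sample1 = colnames(m)[i], sample2 = colnames(m)[j],
               b = b, c = c_, p = .mcnemar_p(b, c_),
               stringsAsFactors = FALSE)
  }))
  comp$significant <- comp$p < alpha / ntest
  sig <- cbind(match(comp$sample1, colnames(m)),
               match(comp$sample2, colnames(m)))[comp$significant, ,
                                                 drop = FALSE]
  structure(list(comparisons = comp,
                 letters = .compact_letters(k, sig, colnames(m)),
                 alpha = alpha, alpha_per_test = alpha / ntest),
            class = "mcnemar_pairwise")
}

#' @export
print.mcnemar_pairwise <- function(x, ...) {
  cat("Pairwise McNemar tests,", nrow(x$comparisons), "comparisons,",
      "Bonferroni alpha per test =", signif(x$alpha_per_test, 3), "\n")
  cat("Letters:", paste(names(x$letters), x$letters, sep = "=",
                        collapse = " "), "\n")
  invisible(x)
}

# Insert-and-absorb compact letter display. `sig` is a 2-column matrix of
# significantly different column indices; groups start as one block and are
# split on each significant pair, then groups nested in others are absorbed.
.compact_letters <- function(k, sig, labels) {
  groups <- list(seq_len(k))
  for (t in seq_len(nrow(sig))) {
    i <- sig[t, 1]; j <- sig[t, 2]
    newg <- list()
    for (g in groups) {
      if (all(c(i, j) %in% g)) newg <- c(newg, list(setdiff(g, i),
                                                    setdiff(g, j)))
      else newg <- c(newg, list(g))
    }
    keep <- rep(TRUE, length(newg))
    for (a in seq_along(newg)) for (b in seq_along(newg))
      if (a != b && keep[b] && all(newg[[a]] %in% newg[[b]]) &&
          (length(newg[[a]]) < length(newg[[b]]) || a > b))
        keep[a] <- FALSE
    groups <- newg[keep]
  }
  groups <- groups[order(vapply(groups, min, 1L))]
  out <- stats::setNames(rep("", k), labels)
  for (g in seq_along(groups))
    out[groups[[g]]] <- paste0(out[groups[[g]]], letters[g])
  out
}

#' Correspondence analysis of a contingency table
#'
#' Standard chi-square correspondence analysis: with correspondence matrix
#' \eqn{P = X / N}, row and column masses \eqn{r, c}, the matrix of
#' standardised residuals \eqn{S = (P - r c') / \sqrt{r c'}} is decomposed
#' by SVD. Squared singular values are the principal inertias; their sum is
#' the table's total inertia \eqn{\chi^2 / N}. Row and column coordinates
#' are principal (scaled by the singular values), so inter-profile
#' chi-square distances are preserved. Inertia proportions are invariant to
#' a global rescaling of the table, so a percent-basis table and its count
#' counterpart decompose identically.
#'
#' @param table a [contingency_table()] or plain non-negative matrix
#'   without all-zero rows or columns (drop them first, e.g. via
#'   `load_emoji_frequencies(drop_zero = TRUE)`).
#' @return list of class `"ca_result"`: `eigenvalues` (principal
#'   inertias), `inertia_prop` (percent of total inertia per dimension),
#'   `cum_prop`, `row_coord`, `col_coord`, `row_mass`, `col_mass`,
#'   `total_inertia`.
#' @examples
#' ca <- correspondence_analysis(load_emoji_frequencies())
#' ca$inertia_prop[1:2]
#' @export
correspondence_analysis <- function(table) {
  X <- unclass(as.matrix(table))
  if (any(X < 0)) stop("contingency entries must be >= 0")
  if (any(rowSums(X) == 0) || any(colSums(X) == 0))
    stop("all-zero rows/columns carry no mass: drop them before CA")
  P <- X / sum(X)
  r <- rowSums(P)
  c_ <- colSums(P)
  S <- (P - r %o% c_) / sqrt(r %o% c_)
  dec <- svd(S)
  ndim <- min(nrow(X), ncol(X)) - 1L
  sv <- dec$d[seq_len(ndim)]
  ev <- sv^2
  total <- sum(ev)
  prop <- if (total > 0) 100 * ev / total else rep(0, ndim)
  rc <- sweep(dec$u[, seq_len(ndim), drop = FALSE] / sqrt(r), 2, sv, `*`)
  cc <- sweep(dec$v[, seq_len(ndim), drop = FALSE] / sqrt(c_), 2, sv, `*`)
  dimnames(rc) <- list(rownames(X), paste0("Dim", seq_len(ndim)))
  dimnames(cc) <- list(colnames(X), paste0("Dim", seq_len(ndim)))
  structure(list(eigenvalues = ev, inertia_prop = prop,
                 cum_prop = cumsum(prop), row_coord = rc, col_coord = cc,
                 row_mass = r, col_mass = c_, total_inertia = total),
            class = "ca_result")
}

#' @export
print.ca_result <- function(x, ...) {
  cat("Correspondence analysis:", nrow(x$row_coord), "rows x",
      nrow(x$col_coord), "columns\n")
  cat("Total inertia (chi-square / N):", signif(x$total_inertia, 6), "\n")
  cat("Inertia by dimension (%):",
      paste(sprintf("%.2f", x$inertia_prop), collapse = " "), "\n")
  invisible(x)
}
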