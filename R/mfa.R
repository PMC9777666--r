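#' Variable group for multiple factor analysis
#'
#' @param name group label (e.g. `"faa"`, `"sensory"`, `"emoji"`).
#' @param data numeric matrix or data frame, samples in rows, variables in
#'   columns; rownames identify samples.
#' @param kind `"continuous"` (z-scored before MFA) or `"frequency"`
#'   (chi-square scaled, as for CATA frequency blocks).
#' @return list of class `"variable_group"`.
#' @export
variable_group <- function(name, data, kind = c("continuous", "frequency")) {
  kind <- match.arg(kind)
  data <- as.matrix(data)
  if (!ncol(data)) stop("a variable group needs at least one variable")
  if (!is.numeric(data)) stop("group data must be numeric")
  structure(list(name = name, data = data, kind = kind),
            class = "variable_group")
}

# Pre-scale one group's block before the global PCA. Continuous blocks are
# column-centered and scaled to unit variance; frequency blocks get the CA
# (chi-square) transform so that mixed data types are comparable.
.scale_block <- function(g) {
  X <- g$data
  if (g$kind == "continuous") {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0))
      stop("constant column(s) in group '", g$name, "': ",
           paste(colnames(X)[sds == 0], collapse = ", "))
    scale(X, center = TRUE, scale = sds)
  } else {
    P <- X / sum(X)
    r <- rowSums(P)
    c_ <- colSums(P)
    if (any(r == 0) || any(c_ == 0))
      stop("all-zero rows/columns in frequency group '", g$name, "'")
    (P - r %o% c_) / sqrt(r %o% c_) * sqrt(length(r))
  }
}

#' Multiple factor analysis of variable groups
#'
#' Each group's block is pre-scaled ([variable_group()] kinds), then
#' divided by its first singular value so that no single group dominates,
#' and the weighted blocks are concatenated and decomposed by a global PCA
#' (SVD of the centered concatenation). This is the classical group
#' weighting of multiple factor analysis: every block contributes at most
#' unit inertia to the first global dimension.
#'
#' @param groups list of [variable_group()]s sharing the same samples in
#'   the same order (>= 2 groups, >= 3 samples).
#' @return list of class `"mfa_result"`: `eigenvalues`, `percent_var`,
#'   `scores` (global sample coordinates), `loadings` (variable weights on
#'   the global dimensions), `group_weights` (inverse first singular value
#'   per group), `groups`.
#' @export
mfa <- function(groups) {
  if (inherits(groups, "variable_group")) groups <- list(groups)
  ns <- vapply(groups, function(g) nrow(g$data), 1L)
  if (length(unique(ns)) != 1)
    stop("groups have mismatched sample counts")
  rn <- lapply(groups, function(g) rownames(g$data))
  if (length(unique(rn[!vapply(rn, is.null, TRUE)])) > 1)
    stop("groups have mismatched sample sets")
  n <- ns[1]
  if (n < 3) stop("need at least three samples")
  blocks <- lapply(groups, .scale_block)
  w <- vapply(blocks, function(B) {
    s1 <- svd(scale(B, center = TRUE, scale = FALSE), nu = 0, nv = 0)$d[1]
    1 / s1
  }, 1)
  Z <- do.call(cbind, Map(function(B, wi) B * wi, blocks, w))
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  dec <- svd(Zc)
  keep <- dec$d > max(dec$d) * 1e-10
  ev <- (dec$d[keep])^2 / (n - 1)
  scores <- dec$u[, keep, drop = FALSE] %*% diag(dec$d[keep],
                                                 sum(keep), sum(keep))
  loadings <- dec$v[, keep, drop = FALSE]
  dimnames(scores) <- list(rownames(groups[[1]]$data),
                           paste0("Dim", seq_len(sum(keep))))
  dimnames(loadings) <- list(colnames(Z), colnames(scores))
  structure(list(eigenvalues = ev,
                 percent_var = 100 * ev / sum(ev),
                 scores = scores, loadings = loadings,
                 group_weights = stats::setNames(
                   w, vapply(groups, `[[`, "", "name")),
                 groups = vapply(groups, `[[`, "", "name")),
            class = "mfa_result")
}

#' @export
print.mfa_result <- function(x, ...) {
  cat("MFA of", length(x$groups), "group(s):",
      paste(x$groups, collapse = ", "), "\n")
  cat("Variance by dimension (%):",
      paste(sprintf("%.2f", x$percent_var), collapse = " "), "\n")
  invisible(x)
}

#' Escoufier's RV coefficient between two data sets
#'
#' A matrix correlation in \[0, 1\] between two column-centered data sets
#' on the same samples:
#' \deqn{RV = \frac{\mathrm{tr}(X X' Y Y')}
#'   {\sqrt{\mathrm{tr}((X X')^2)\,\mathrm{tr}((Y Y')^2)}}}
#' RV is invariant to rotation and isotropic scaling of either set and is
#' the group-association measure conventionally read alongside MFA. The
#' study's banding is exposed by [rv_band()]: below 0.6 low, 0.6-0.7
#' moderate, above 0.7 high.
#'
#' @param X,Y numeric matrices with equal row counts (columns are centered
#'   internally).
#' @return the RV coefficient.
#' @export
rv_coefficient <- function(X, Y) {
  X <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  Y <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same sample count")
  Wx <- tcrossprod(X)
  Wy <- tcrossprod(Y)
  den <- sqrt(sum(Wx * Wx) * sum(Wy * Wy))
  if (den == 0) stop("RV undefined for an all-constant matrix")
  sum(Wx * Wy) / den
}

#' @rdname rv_coefficient
#' @param rv numeric vector of RV coefficients.
#' @return `rv_band()`: factor with levels `low`, `moderate`, `high`.
#' @export
rv_band <- function(rv) {
  factor(ifelse(rv < 0.6, "low", ifelse(rv <= 0.7, "moderate", "high")),
         levels = c("low", "moderate", "high"))
}

#' Pairwise RV matrix over variable groups
#'
#' @param groups list of [variable_group()]s.
#' @return symmetric matrix of class `"rv_matrix"` with unit diagonal.
#' @export
rv_matrix <- function(groups) {
  k <- length(groups)
  nm <- vapply(groups, `[[`, "", "name")
  m <- diag(1, k)
  dimnames(m) <- list(nm, nm)
  if (k > 1)
    for (i in 1:(k - 1)) for (j in (i + 1):k)
      m[i, j] <- m[j, i] <- rv_coefficient(groups[[i]]$data,
                                           groups[[j]]$data)
  structure(m, class = c("rv_matrix", class(m)))
}

#' Export an RV matrix as network files
#'
#' Writes a node table (`nodes.csv`), a weighted edge list (`edges.csv`,
#' with the correlation band and an edge width proportional to RV) and a
#' SIF file (`network.sif`) for import into network viewers such as
#' Cytoscape. Self-edges are never written.
#'
#' @param rv an [rv_matrix()] (or any symmetric matrix with dimnames).
#' @param dir output directory (created if absent).
#' @return invisibly, the edge data frame.
#' @export
export_network <- function(rv, dir) {
  m <- unclass(as.matrix(rv))
  nm <- rownames(m)
  if (is.null(nm)) stop("RV matrix needs dimnames")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  k <- nrow(m)
  pairs <- utils::combn(k, 2)
  edges <- data.frame(source = nm[pairs[1, ]], target = nm[pairs[2, ]],
                      rv = m[cbind(pairs[1, ], pairs[2, ])],
                      stringsAsFactors = FALSE)
  edges$band <- as.character(rv_band(edges$rv))
  edges$width <- edges$rv * 10
  utils::write.csv(data.frame(node = nm), file.path(dir, "nodes.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(edges, file.path(dir, "edges.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(sprintf("%s rv %s", edges$source, edges$target),
             file.path(dir, "network.sif"))
  invisible(edges)
}
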