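#' Replicate-level compound concentration table
#'
#' A `compound_table` is a long-form data frame of per-replicate taste
#' compound concentrations with columns `sample`, `replicate`, `compound`,
#' `value` (mg/100 g) and `detected`. Values reported as not determined
#' (sentinel `"ND"` in CSV input) are stored as `value = 0`,
#' `detected = FALSE`, so they contribute zero to category sums and to EUC.
#'
#' @param records data frame with columns `sample`, `replicate`, `compound`,
#'   `value` and optionally `detected` (default `TRUE`).
#' @return the validated records with class `"compound_table"`.
#' @seealso [read_compound_csv()], [summarize_replicates()]
#' @export
compound_table <- function(records) {
  req <- c("sample", "replicate", "compound", "value")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(records$detected)) records$detected <- TRUE
  records <- records[c(req, "detected")]
  parse_sample_key(unique(records$sample))
  bad <- setdiff(records$compound, compound_vocabulary()$compound)
  if (length(bad))
    stop("unknown compound identifier(s): ", paste(bad, collapse = ", "))
  records$value <- as.numeric(records$value)
  records$replicate <- as.integer(records$replicate)
  if (anyNA(records$value)) stop("non-numeric concentration value")
  if (any(records$value < 0)) stop("negative concentration value")
  if (any(records$replicate < 1)) stop("replicate indices must be positive")
  if (any(records$value != 0 & !records$detected))
    stop("non-detected records must carry value 0")
  structure(records, class = c("compound_table", "data.frame"))
}

#' Read or write a replicate-level concentration CSV
#'
#' The CSV dialect is long form with header `sample,replicate,compound,value`;
#' `value` is numeric in mg/100 g or the sentinel `"ND"` for below-detection
#' cells.
#'
#' @param path file path.
#' @return [read_compound_csv()] returns a [compound_table()].
#' @export
read_compound_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  req <- c("sample", "replicate", "compound", "value")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("compound CSV is missing column(s): ", paste(miss, collapse = ", "))
  nd <- df$value == "ND"
  df$detected <- !nd
  df$value[nd] <- "0"
  val <- suppressWarnings(as.numeric(df$value))
  if (anyNA(val)) stop("non-numeric value (use the sentinel \"ND\")")
  df$value <- val
  compound_table(df)
}

#' @rdname read_compound_csv
#' @param table a [compound_table()].
#' @export
write_compound_csv <- function(table, path) {
  stopifnot(inherits(table, "compound_table"))
  out <- as.data.frame(table)[c("sample", "replicate", "compound", "value")]
  out$value <- ifelse(table$detected, format(table$value, trim = TRUE), "ND")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-cell replicate summary (mean, SD, n)
#'
#' Collapses a replicate-level [compound_table()] to one row per
#' (sample, compound) with the replicate mean, sample standard deviation
#' (n - 1 denominator; 0 for a single replicate) and replicate count,
#' mirroring the mean +/- SD presentation of the study's compound table.
#'
#' @param table a [compound_table()].
#' @return data frame of class `"sample_summary"` with columns `sample`,
#'   `compound`, `mean`, `sd`, `n`, `detected`.
#' @export
summarize_replicates <- function(table) {
  stopifnot(inherits(table, "compound_table"))
  if (!nrow(table)) stop("empty compound table")
  key <- interaction(table$sample, table$compound, drop = TRUE)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(table)), key), function(i) {
    v <- table$value[i]
    data.frame(sample = table$sample[i[1]], compound = table$compound[i[1]],
               mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               n = length(v),
               detected = any(table$detected[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  sample_summary(agg)
}

#' @rdname summarize_replicates
#' @param df data frame with columns `sample`, `compound`, `mean`, `sd`,
#'   and optionally `n` (default 1) and `detected` (default `TRUE`); used to
#'   construct a summary directly from published mean +/- SD cells.
#' @export
sample_summary <- function(df) {
  req <- c("sample", "compound", "mean", "sd")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$n)) df$n <- 1L
  if (is.null(df$detected)) df$detected <- TRUE
  df <- df[c(req, "n", "detected")]
  parse_sample_key(unique(df$sample))
  if (any(df$sd < 0)) stop("negative standard deviation")
  if (any(df$n < 1)) stop("replicate count must be >= 1")
  structure(df, class = c("sample_summary", "data.frame"))
}

#' Packaged compound summary of the nine crab samples
#'
#' Mean +/- SD concentrations (n = 3 replicates) of the 26 taste compounds
#' in the nine (part x origin x variety) samples, transcribed from the
#' study's compound table. Hepatopancreas GMP/IMP/AMP cells below the
#' detection limit are stored as `mean = 0`, `detected = FALSE`.
#'
#' @return `load_crab_compounds()`: a [sample_summary()] (9 samples x 26
#'   compounds).
#' @examples
#' head(load_crab_compounds())
#' @export
load_crab_compounds <- function() {
  path <- system.file("extdata", "crab_compound_means.csv", package = "umamipanel",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  nd <- df$mean == "ND"
  df$detected <- !nd
  df$mean[nd] <- "0"
  df$sd[nd] <- "0"
  df$mean <- as.numeric(df$mean)
  df$sd <- as.numeric(df$sd)
  df$n <- 3L
  sample_summary(df)
}

#' @rdname load_crab_compounds
#' @return `load_crab_printed_sums()`: the published per-sample category
#'   sums (`UFAA`, `SFAA`, `BFAA`, `FAA`, in mg/100 g) and `EUC`
#'   (g MSG/100 g) as a data frame with columns `row`, `sample`, `mean`,
#'   `sd`; used to cross-check recomputed quantities.
#' @export
load_crab_printed_sums <- function() {
  path <- system.file("extdata", "crab_printed_sums.csv",
                      package = "umamipanel", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Sum of mean concentrations over a taste category
#'
#' @param summary a [sample_summary()].
#' @param category one of `"umami"`, `"sweet"`, `"bitter"`,
#'   `"uncategorized"`, or the pseudo-category `"total"` which sums all 17
#'   free amino acids.
#' @param sample a sample code, e.g. `"M-C-JH"`.
#' @param scheme category scheme passed to [faa_categories()].
#' @return the summed mean concentration in mg/100 g.
#' @examples
#' s <- load_crab_compounds()
#' category_sum(s, "umami", "M-C-JH")  # 73.24
#' @export
category_sum <- function(summary, category, sample,
                         scheme = c("table", "text")) {
  stopifnot(inherits(summary, "sample_summary"))
  cats <- faa_categories(match.arg(scheme))
  members <- if (identical(category, "total"))
    compound_vocabulary()$compound[compound_vocabulary()$class == "faa"]
  else if (category %in% names(cats)) cats[[category]]
  else stop("unknown category: ", category)
  rows <- summary$sample == sample & summary$compound %in% members
  sum(summary$mean[rows])
}

#' All category sums as a category x sample table
#'
#' @inheritParams category_sum
#' @return data frame with one row per category (`umami`, `sweet`, `bitter`,
#'   `uncategorized`, `total`) and one column per sample present in
#'   `summary`.
#' @export
category_sums <- function(summary, scheme = c("table", "text")) {
  scheme <- match.arg(scheme)
  samples <- intersect(crab_samples(), unique(summary$sample))
  cats <- c(names(faa_categories(scheme)), "total")
  out <- sapply(samples, function(s)
    sapply(cats, function(ct) category_sum(summary, ct, s, scheme)))
  data.frame(category = cats, out, check.names = FALSE, row.names = NULL)
}
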