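#' Study design: sample keys and compound vocabulary
#'
#' The study design crosses three edible parts of the Chinese mitten crab
#' with two farming origins and two selected varieties, but only nine
#' combinations exist: the Chongming farm reared only the Jianghai 21
#' variety, while the Taixing farm reared both Jianghai 21 and Yangtze II.
#' Sample codes are `"<part>-<origin>-<variety>"`, e.g. `"M-C-JH"` is
#' abdomen meat of a Chongming-reared Jianghai 21 crab.
#'
#' @return `crab_samples()` returns the nine sample codes in study order
#'   (meat, hepatopancreas, gonad; within each part C-JH, T-JH, T-CJ).
#' @examples
#' crab_samples()
#' parse_sample_key("G-T-CJ")
#' @export
crab_samples <- function() {
  as.vector(outer(c("C-JH", "T-JH", "T-CJ"), c("M", "H", "G"),
                  function(ov, p) paste(p, ov, sep = "-")))
}

.part_labels <- c(M = "abdomen meat", H = "hepatopancreas", G = "gonad")
.origin_labels <- c(C = "Chongming", T = "Taixing")
.variety_labels <- c(JH = "Jianghai 21", CJ = "Yangtze II")

#' @rdname crab_samples
#' @param x character vector of sample codes.
#' @return `parse_sample_key()` returns a data frame with columns `sample`,
#'   `part`, `origin`, `variety`; it errors on codes outside the nine-sample
#'   design (in particular `C` paired with `CJ`, which was never reared).
#' @export
parse_sample_key <- function(x) {
  bad <- setdiff(x, crab_samples())
  if (length(bad))
    stop("unknown sample code(s): ", paste(bad, collapse = ", "),
         " (valid: ", paste(crab_samples(), collapse = ", "), ")")
  parts <- do.call(rbind, strsplit(x, "-", fixed = TRUE))
  data.frame(sample = x,
             part = parts[, 1], origin = parts[, 2], variety = parts[, 3],
             stringsAsFactors = FALSE)
}

#' Controlled vocabulary of taste compounds
#'
#' The 26 quantified taste compounds: 17 free amino acids (FAA), five
#' 5'-nucleotide-related compounds (GMP, IMP, AMP and the ATP degradation
#' products Hx and HxR), and four metal ions. Ions are keyed by element
#' symbol (`"K"` is the potassium cation).
#'
#' @return data frame with columns `compound` and `class`
#'   (`"faa"`, `"nucleotide"`, `"ion"`).
#' @examples
#' table(compound_vocabulary()$class)
#' @export
compound_vocabulary <- function() {
  data.frame(
    compound = c("Asp", "Glu", "Thr", "Ser", "Gly", "Ala", "Arg", "Pro",
                 "Val", "Met", "Leu", "Tyr", "Phe", "Lys", "His", "Ile",
                 "Cys",
                 "GMP", "IMP", "AMP", "Hx", "HxR",
                 "Na", "K", "Mg", "Ca"),
    class = rep(c("faa", "nucleotide", "ion"), c(17, 5, 4)),
    stringsAsFactors = FALSE)
}

#' Taste categories of the free amino acids
#'
#' Two built-in membership schemes are shipped because the study's summary
#' rows and its prose disagree slightly:
#' \describe{
#'   \item{`"table"`}{reproduces the printed category sums exactly:
#'     umami = \{Asp, Glu\}, sweet = \{Thr, Ser, Gly, Ala, Pro, Arg\},
#'     bitter = \{Val, Leu, Tyr, Phe, Lys, His, Ile\}, leaving Met and Cys
#'     uncategorized. This is the default and the scheme used throughout
#'     the package's worked analyses.}
#'   \item{`"text"`}{follows the narrative classification, which counts Met
#'     as bitter and does not list Arg as sweet.}
#' }
#' Neither convention is asserted as chemically "correct"; the `"table"`
#' scheme is preferred only because the printed sums verify it.
#'
#' @param scheme `"table"` (default) or `"text"`.
#' @return named list of character vectors with elements `umami`, `sweet`,
#'   `bitter`, `uncategorized`; the categories are disjoint and their union
#'   is contained in the 17 FAAs.
#' @examples
#' faa_categories()$umami
#' setdiff(faa_categories("text")$bitter, faa_categories("table")$bitter)
#' @export
faa_categories <- function(scheme = c("table", "text")) {
  scheme <- match.arg(scheme)
  if (scheme == "table")
    list(umami = c("Asp", "Glu"),
         sweet = c("Thr", "Ser", "Gly", "Ala", "Pro", "Arg"),
         bitter = c("Val", "Leu", "Tyr", "Phe", "Lys", "His", "Ile"),
         uncategorized = c("Met", "Cys"))
  else
    list(umami = c("Glu", "Asp"),
         sweet = c("Thr", "Ser", "Gly", "Ala", "Pro"),
         bitter = c("Val", "Met", "Leu", "Tyr", "Phe", "Lys", "His", "Ile"),
         uncategorized = c("Arg", "Cys"))
}
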