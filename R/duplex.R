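#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")
WC_PARTNER <- c(A = "T", C = "G", G = "C", T = "A")
PURINES <- c("A", "G")

#' Names of the six binary-combination duplex presets
#'
#' The six 12-bp model duplexes cover all binary combinations of nucleotides
#' in the 5'->3' strand: `ds-poly(XY-X'Y')` repeats the dinucleotide `XY` six
#' times, with `X'Y'` the Watson-Crick complements.
#'
#' @return Character vector of the six preset names.
#' @export
duplex_presets <- function() {
  c("ds-poly(AA-TT)", "ds-poly(AT-TA)", "ds-poly(GG-CC)",
    "ds-poly(GC-CG)", "ds-poly(GA-CT)", "ds-poly(GT-CA)")
}

#' Construct a 12-bp model DNA duplex with its 8-base analysis region
#'
#' Builds one of the repeating-dinucleotide model duplexes: the 5'->3' strand
#' is the dinucleotide repeated six times and the complementary strand is its
#' exact Watson-Crick complement (no mismatches). The analysis (QM1) region
#' comprises eight nucleobases: the central four bases of the 5'->3' strand
#' (base-pair positions 5-8) plus their partners on the opposite strand.
#' All charge and hole analysis in the package is restricted to this region.
#'
#' @param x Either one of the preset names from [duplex_presets()] (e.g.
#'   `"ds-poly(GG-CC)"`) or an explicit dinucleotide such as `"GA"`, which is
#'   equivalent to the corresponding preset.
#'
#' @return An object of class `dna_duplex` with components:
#'   \describe{
#'     \item{name}{canonical preset-style name}
#'     \item{strand53}{12-base sequence of the 5'->3' strand}
#'     \item{strand35}{its Watson-Crick complement, indexed by base pair}
#'     \item{pairing}{data frame mapping each base-pair position to the two
#'       paired bases}
#'     \item{qm1_indices}{the base-pair positions (5:8) of the analysis region}
#'     \item{qm1}{data frame with one row per analysis-region base (8 rows):
#'       slot, label (e.g. `"A5"`), strand, pair position, base letter,
#'       purine flag, and whether the base sits in a same-strand stacked
#'       purine-purine pair}
#'     \item{stacking_pairs}{data frame of same-strand adjacent base pairs
#'       within the analysis region, flagged purine-purine or not}
#'     \item{arrangement}{`"stacked"`, `"diagonal"` or `"none"` describing the
#'       purine arrangement in the analysis region}
#'   }
#' @examples
#' sys <- dna_duplex("ds-poly(GA-CT)")
#' sys$arrangement  # purines G and A stack on the same strand
#' @export
dna_duplex <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  xy <- parse_duplex_name(x)
  letters <- strsplit(xy, "")[[1]]
  bad <- which(!letters %in% DNA_BASES)
  if (length(bad)) {
    stopf("unknown base letter '%s' at position %d of '%s'", letters[bad[1]], bad[1], xy)
  }
  strand53 <- strrep(xy, 6L)
  b53 <- strsplit(strand53, "")[[1]]
  b35 <- unname(WC_PARTNER[b53])
  strand35 <- paste(b35, collapse = "")
  name <- sprintf("ds-poly(%s-%s)", xy, paste(WC_PARTNER[letters], collapse = ""))

  pairing <- data.frame(pair = 1:12, base53 = b53, base35 = b35,
                        stringsAsFactors = FALSE)
  qm1_indices <- 5:8
  qm1 <- data.frame(
    slot = 1:8,
    label = c(paste0("A", qm1_indices), paste0("B", qm1_indices)),
    strand = rep(c("A", "B"), each = 4L),
    pair = rep(qm1_indices, 2L),
    base = c(b53[qm1_indices], b35[qm1_indices]),
    stringsAsFactors = FALSE
  )
  qm1$purine <- qm1$base %in% PURINES

  # same-strand adjacent base pairs inside the analysis region
  adj <- do.call(rbind, lapply(c("A", "B"), function(s) {
    idx <- which(qm1$strand == s)
    data.frame(i = idx[-length(idx)], j = idx[-1L])
  }))
  stacking_pairs <- data.frame(
    i = adj$i, j = adj$j,
    label_i = qm1$label[adj$i], label_j = qm1$label[adj$j],
    base_i = qm1$base[adj$i], base_j = qm1$base[adj$j],
    purine_purine = qm1$purine[adj$i] & qm1$purine[adj$j],
    stringsAsFactors = FALSE
  )
  qm1$stacked_purine <- vapply(qm1$slot, function(s) {
    any(stacking_pairs$purine_purine & (stacking_pairs$i == s | stacking_pairs$j == s))
  }, logical(1))

  sys <- structure(
    list(name = name, strand53 = strand53, strand35 = strand35,
         pairing = pairing, qm1_indices = qm1_indices, qm1 = qm1,
         stacking_pairs = stacking_pairs),
    class = "dna_duplex"
  )
  sys$arrangement <- purine_arrangement(sys)
  sys
}

# Accept "XY" or "ds-poly(XY-X'Y')"; check the declared complement if given.
parse_duplex_name <- function(x) {
  if (grepl("^ds-poly\\(..-..\\)$", x)) {
    inner <- sub("^ds-poly\\((..)-(..)\\)$", "\\1 \\2", x)
    parts <- strsplit(inner, " ")[[1]]
    xy <- parts[1]
    letters <- strsplit(xy, "")[[1]]
    bad <- which(!letters %in% DNA_BASES)
    if (length(bad)) {
      stopf("unknown base letter '%s' at position %d of '%s'", letters[bad[1]], bad[1], x)
    }
    expected <- paste(WC_PARTNER[letters], collapse = "")
    if (!identical(parts[2], expected)) {
      stopf("'%s' is not Watson-Crick complementary: %s pairs with %s", x, xy, expected)
    }
    return(xy)
  }
  if (nchar(x) == 2L) return(toupper(x))
  stopf("cannot interpret '%s' as a duplex preset or dinucleotide", x)
}

# Purine arrangement in the analysis region: same-strand stacked pairs beat
# cross-strand diagonal contacts; "none" kept for completeness.
purine_arrangement <- function(system) {
  stopifnot(inherits(system, "dna_duplex"))
  if (any(system$stacking_pairs$purine_purine)) return("stacked")
  q <- system$qm1
  for (p in system$qm1_indices[-length(system$qm1_indices)]) {
    a_here <- q$purine[q$strand == "A" & q$pair == p]
    b_next <- q$purine[q$strand == "B" & q$pair == p + 1L]
    b_here <- q$purine[q$strand == "B" & q$pair == p]
    a_next <- q$purine[q$strand == "A" & q$pair == p + 1L]
    if ((a_here && b_next) || (b_here && a_next)) return("diagonal")
  }
  "none"
}

#' @export
print.dna_duplex <- function(x, ...) {
  cat(sprintf("%s: 12-bp model DNA duplex\n", x$name))
  cat(sprintf("  5'-%s-3'\n  3'-%s-5'\n", x$strand53, x$strand35))
  cat(sprintf("  analysis region: pairs %s (%s)\n",
              paste(range(x$qm1_indices), collapse = "-"),
              paste(x$qm1$label, "=", x$qm1$base, collapse = ", ")))
  cat(sprintf("  purine arrangement: %s\n", x$arrangement))
  invisible(x)
}
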