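# Three-letter <-> one-letter amino-acid code tables. "Ter"/"*" denotes a
# translation stop.
AA3 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
  Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
  Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
  Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
  Ter = "*"
)
AA1 <- stats::setNames(names(AA3), AA3)

aa_to_one <- function(x) {
  out <- unname(AA3[x])
  if (anyNA(out)) stop("unknown residue code: ", paste(x[is.na(out)], collapse = ", "))
  out
}

aa_to_three <- function(x) {
  out <- unname(AA1[x])
  if (anyNA(out)) stop("unknown residue code: ", paste(x[is.na(out)], collapse = ", "))
  out
}

#' Represent a protein-coding ORF and its sequencing tiles
#'
#' Builds an ORF object from a DNA coding sequence, deriving the protein
#' sequence by standard-genetic-code translation and partitioning the codons
#' into contiguous sequencing tiles. Tiled mutagenesis sequencing amplifies
#' ~150 bp amplicons whose primer-flanked, variant-readable inserts cover
#' about 100 bp each, so a SOD1-sized 154-codon ORF yields 5 tiles.
#'
#' @param nucleotides Character scalar, DNA coding sequence. Must start with
#'   ATG, have length divisible by 3, and contain no internal stop codons.
#'   A trailing stop codon is allowed and trimmed.
#' @param tile_insert_bp Target variant-readable insert length per tile in
#'   base pairs; tiles are defined on codon boundaries.
#' @return An object of class `orf_sequence`: list with `nucleotides`,
#'   `protein` (one-letter string, no stop), `n_codons`, and `tiles`, a
#'   data frame of half-open codon ranges (`tile`, `start`, `end`).
#' @examples
#' orf <- orf_sequence(paste0("ATG", strrep("GCT", 9)))
#' orf$protein
#' @export
orf_sequence <- function(nucleotides, tile_insert_bp = 100) {
  nucleotides <- toupper(gsub("\\s", "", nucleotides))
  if (!grepl("^[ACGT]+$", nucleotides)) stop("ORF must contain only A/C/G/T")
  if (nchar(nucleotides) %% 3 != 0) stop("ORF length must be divisible by 3")
  if (substr(nucleotides, 1, 3) != "ATG") stop("ORF must start with ATG")
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(nucleotides)))
  # trailing stop is fine; internal stops are not
  if (substr(prot, nchar(prot), nchar(prot)) == "*") {
    prot <- substr(prot, 1, nchar(prot) - 1L)
    nucleotides <- substr(nucleotides, 1, nchar(nucleotides) - 3L)
  }
  if (grepl("\\*", prot)) stop("ORF contains an internal stop codon")
  n_codons <- nchar(prot)
  n_tiles <- max(1L, round(n_codons * 3 / tile_insert_bp))
  # spread codons as evenly as possible over n_tiles contiguous ranges
  sizes <- rep(n_codons %/% n_tiles, n_tiles)
  extra <- n_codons %% n_tiles
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  tiles <- data.frame(
    tile = seq_len(n_tiles),
    start = c(1L, ends[-n_tiles] + 1L),
    end = ends
  )
  structure(
    list(nucleotides = nucleotides, protein = prot,
         n_codons = n_codons, tiles = tiles),
    class = "orf_sequence"
  )
}

#' @export
print.orf_sequence <- function(x, ...) {
  cat(sprintf("ORF: %d codons, %d tiles\n", x$n_codons, nrow(x$tiles)))
  invisible(x)
}

codon_at <- function(orf, pos) {
  substr(orf$nucleotides, 3 * (pos - 1) + 1, 3 * pos)
}

tile_of_position <- function(orf, pos) {
  t <- orf$tiles
  idx <- findInterval(pos, t$start)
  idx[pos < 1 | pos > orf$n_codons] <- NA_integer_
  t$tile[idx]
}

#' Parse protein variant notation
#'
#' Parses HGVS-style protein substitution notation such as `"p.Ala5Val"`
#' into its components. Both three-letter and one-letter residue codes are
#' accepted (`"p.A5V"`), as are `"Ter"` and `"*"` for a stop gain. The
#' leading `"p."` is optional on input.
#'
#' @param text Character vector of variant notations.
#' @return A data frame with columns `variant` (canonical three-letter
#'   form), `position`, `ref_aa`, `alt_aa` (one-letter, `*` = stop) and
#'   `klass` (`missense`, `nonsense` or `synonymous`).
#' @examples
#' parse_variant(c("p.Ala5Val", "p.Gly130Ser", "G94R"))
#' @export
parse_variant <- function(text) {
  text0 <- text
  text <- sub("^p\\.", "", text)
  m <- regmatches(text, regexec("^([A-Za-z]{3}|[A-Z*])([0-9]+)([A-Za-z]{3}|[A-Z*])$", text))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) stop("cannot parse variant notation: ", paste(text0[bad], collapse = ", "))
  ref <- vapply(m, `[`, "", 2L)
  pos <- as.integer(vapply(m, `[`, "", 3L))
  alt <- vapply(m, `[`, "", 4L)
  to_one <- function(x) {
    out <- character(length(x))
    three <- nchar(x) == 3
    out[three] <- aa_to_one(x[three])
    bad <- !three & !(x %in% names(AA1))
    if (any(bad)) stop("unknown residue code: ", paste(x[bad], collapse = ", "))
    out[!three] <- x[!three]
    out
  }
  ref1 <- to_one(ref)
  alt1 <- to_one(alt)
  if (any(pos < 1)) stop("non-positive variant position: ",
                         paste(text0[pos < 1], collapse = ", "))
  if (any(ref1 == "*")) stop("reference residue cannot be a stop: ",
                             paste(text0[ref1 == "*"], collapse = ", "))
  klass <- ifelse(alt1 == "*", "nonsense",
                  ifelse(alt1 == ref1, "synonymous", "missense"))
  data.frame(
    variant = format_variant(pos, ref1, alt1),
    position = pos, ref_aa = ref1, alt_aa = alt1, klass = klass,
    stringsAsFactors = FALSE
  )
}

#' Format variants in canonical three-letter notation
#'
#' @param position Integer vector of 1-based residue positions.
#' @param ref_aa,alt_aa One-letter residue codes (`*` = stop).
#' @return Character vector like `"p.Ala5Val"`.
#' @export
format_variant <- function(position, ref_aa, alt_aa) {
  paste0("p.", aa_to_three(ref_aa), position, aa_to_three(alt_aa))
}

#' Classify a protein variant against an ORF
#'
#' @param v Data frame as returned by [parse_variant()] (columns `position`,
#'   `ref_aa`, `alt_aa`).
#' @param orf An [orf_sequence()].
#' @return Character vector of classes (`missense`/`nonsense`/`synonymous`).
#' @export
classify_variant <- function(v, orf) {
  if (any(v$position > orf$n_codons))
    stop("variant position beyond protein length ", orf$n_codons)
  ref <- substring(orf$protein, v$position, v$position)
  if (any(ref != v$ref_aa)) {
    i <- which(ref != v$ref_aa)[1]
    stop(sprintf("reference mismatch at position %d: ORF has %s, variant claims %s",
                 v$position[i], ref[i], v$ref_aa[i]))
  }
  ifelse(v$alt_aa == "*", "nonsense",
         ifelse(v$alt_aa == v$ref_aa, "synonymous", "missense"))
}

BASES <- c("A", "C", "G", "T")

# Amino acids (plus stop) encodable by an NNK codon (third base G or T).
nnk_amino_acids <- function() {
  codons <- as.vector(outer(outer(BASES, BASES, paste0), c("G", "T"), paste0))
  unique(unname(Biostrings::GENETIC_CODE[codons]))
}

# Amino acids reachable from `codon` by a single-nucleotide change.
snv_amino_acids <- function(codon) {
  stopifnot(nchar(codon) == 3)
  muts <- character(0)
  for (i in 1:3) {
    for (b in setdiff(BASES, substr(codon, i, i))) {
      mut <- codon
      substr(mut, i, i) <- b
      muts <- c(muts, mut)
    }
  }
  unique(unname(Biostrings::GENETIC_CODE[muts]))
}

#' Enumerate the protein-level variant space of an ORF
#'
#' Lists every amino-acid substitution, stop gain and synonymous change at
#' every codon (21 protein-level classes per codon: 19 missense, 1 nonsense,
#' 1 synonymous; codon-level multiplicity is collapsed). Each entry is
#' flagged for accessibility via an NNK degenerate codon (third base G/T,
#' the saturation-mutagenesis design, which encodes all 20 amino acids and
#' the TAG stop) and via a single-nucleotide variant of the reference codon.
#'
#' @param orf An [orf_sequence()].
#' @return Data frame with columns `variant`, `position`, `ref_aa`,
#'   `alt_aa`, `klass`, `tile`, `nnk_accessible`, `snv_accessible`,
#'   `start_codon` (position 1, excluded from downstream analyses by
#'   default) and `terminal_stop` (stop gain at the final codon, which
#'   cannot anchor nonsense medians meaningfully).
#' @examples
#' space <- enumerate_variant_space(orf_sequence(paste0("ATG", strrep("GGT", 5))))
#' table(space$klass)
#' @export
enumerate_variant_space <- function(orf) {
  aas <- unname(AA3[setdiff(names(AA3), "Ter")])  # one-letter, 20 amino acids
  nnk_set <- nnk_amino_acids()
  n <- orf$n_codons
  rows <- vector("list", n)
  for (pos in seq_len(n)) {
    ref <- substring(orf$protein, pos, pos)
    alts <- c(setdiff(aas, ref), "*", ref)
    klass <- c(rep("missense", 19), "nonsense", "synonymous")
    snv_set <- snv_amino_acids(codon_at(orf, pos))
    rows[[pos]] <- data.frame(
      position = pos, ref_aa = ref, alt_aa = alts, klass = klass,
      nnk_accessible = alts %in% nnk_set,
      snv_accessible = alts %in% snv_set,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$variant <- format_variant(out$position, out$ref_aa, out$alt_aa)
  out$tile <- tile_of_position(orf, out$position)
  out$start_codon <- out$position == 1L
  out$terminal_stop <- out$klass == "nonsense" & out$position == n
  out[, c("variant", "position", "ref_aa", "alt_aa", "klass", "tile",
          "nnk_accessible", "snv_accessible", "start_codon", "terminal_stop")]
}

#' Read a single-record ORF FASTA file
#'
#' @param path Path to a FASTA file with exactly one DNA record.
#' @param ... Passed to [orf_sequence()].
#' @return An [orf_sequence()].
#' @export
read_orf_fasta <- function(path, ...) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 1) stop("expected exactly one FASTA record, found ", length(seqs))
  orf_sequence(as.character(seqs[[1]]), ...)
}

#' Write a variant space table to TSV
#'
#' @param space Data frame from [enumerate_variant_space()].
#' @param path Output path.
#' @export
write_variant_space <- function(space, path) {
  utils::write.table(space, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
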