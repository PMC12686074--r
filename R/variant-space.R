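#' Read a protein sequence from a FASTA file
#'
#' Reads the first record of a FASTA file and validates that every residue
#' is one of the 20 canonical one-letter amino-acid codes. Lowercase input
#' is uppercased. Residue numbering throughout the package is 1-based on
#' this sequence; no isoform mapping is performed, so the supplied FASTA
#' must use the same numbering as any variant labels and score tables.
#'
#' @param path Path to a FASTA file with at least one record.
#' @return A `protein_seq` object: a list with elements `id`, `residues`
#'   (one-letter string) and `length` (residue count).
#' @seealso [protein_seq()], [enumerate_saturation()]
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Package 'Biostrings' is required to read FASTA files.")
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(sprintf("FASTA file has no records: %s", path))
  protein_seq(as.character(set[[1]]), id = names(set)[1])
}

#' Construct a protein sequence object
#'
#' @param residues One-letter amino-acid string (canonical codes only).
#' @param id Sequence identifier.
#' @return A `protein_seq` object.
#' @export
protein_seq <- function(residues, id = "protein") {
  if (!is.character(residues) || length(residues) != 1L || nchar(residues) == 0L) {
    abort("`residues` must be a single non-empty string.")
  }
  residues <- toupper(residues)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_CODES)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Invalid amino-acid code '%s' at position %d (and %d more).",
      chars[bad[1]], bad[1], length(bad) - 1L
    ))
  }
  structure(
    list(id = id, residues = residues, length = nchar(residues)),
    class = "protein_seq"
  )
}

#' @export
print.protein_seq <- function(x, ...) {
  cat(sprintf("<protein_seq> %s: %d residues\n", x$id, x$length))
  invisible(x)
}

residues_of <- function(protein) {
  strsplit(protein$residues, "", fixed = TRUE)[[1]]
}

#' Parse missense variant labels
#'
#' Parses HGVS-p short labels such as `"p.V464M"` (the `"p."` prefix is
#' optional) into a tibble of single-residue substitutions. Synonymous
#' labels (reference equal to alternate) and malformed labels are errors.
#' When a protein is supplied, positions are range-checked and the stated
#' reference residue is checked against the sequence.
#'
#' @param labels Character vector of variant labels.
#' @param protein Optional [protein_seq()] used to validate positions and
#'   reference residues.
#' @return A tibble with columns `variant` (canonical `p.<ref><pos><alt>`
#'   label), `position`, `ref_aa`, `alt_aa`.
#' @examples
#' parse_variants(c("p.V464M", "A634D"))
#' @export
parse_variants <- function(labels, protein = NULL) {
  if (length(labels) == 0L) {
    return(tibble(variant = character(), position = integer(),
                  ref_aa = character(), alt_aa = character()))
  }
  m <- stringr::str_match(labels, "^(?:p\\.)?([A-Za-z])([0-9]+)([A-Za-z])$")
  bad <- which(is.na(m[, 1]))
  if (length(bad) > 0L) {
    abort(sprintf("Malformed variant label: '%s'", labels[bad[1]]))
  }
  ref <- toupper(m[, 2])
  pos <- as.integer(m[, 3])
  alt <- toupper(m[, 4])
  bad_aa <- which(!(ref %in% AA_CODES) | !(alt %in% AA_CODES))
  if (length(bad_aa) > 0L) {
    abort(sprintf("Non-canonical amino acid in label '%s'", labels[bad_aa[1]]))
  }
  syn <- which(ref == alt)
  if (length(syn) > 0L) {
    abort(sprintf("Synonymous label '%s': reference and alternate are identical.",
                  labels[syn[1]]))
  }
  if (!is.null(protein)) {
    out_of_range <- which(pos < 1L | pos > protein$length)
    if (length(out_of_range) > 0L) {
      abort(sprintf("Position %d in '%s' outside sequence of length %d.",
                    pos[out_of_range[1]], labels[out_of_range[1]], protein$length))
    }
    seq_res <- residues_of(protein)
    mism <- which(seq_res[pos] != ref)
    if (length(mism) > 0L) {
      abort(sprintf(
        "Reference mismatch in '%s': sequence has %s at position %d.",
        labels[mism[1]], seq_res[pos[mism[1]]], pos[mism[1]]
      ))
    }
  }
  tibble(
    variant = format_variant(pos, ref, alt),
    position = pos, ref_aa = ref, alt_aa = alt
  )
}

#' Format variants as canonical HGVS-p short labels
#'
#' @param position Integer residue positions (1-based).
#' @param ref_aa,alt_aa One-letter reference/alternate codes.
#' @return Character vector of `p.<ref><pos><alt>` labels. Parsing a
#'   formatted label with [parse_variants()] round-trips exactly.
#' @export
format_variant <- function(position, ref_aa, alt_aa) {
  sprintf("p.%s%d%s", ref_aa, as.integer(position), alt_aa)
}

#' Enumerate the in silico saturation-mutagenesis variant space
#'
#' Substitutes each residue of the protein with all 19 alternative
#' canonical amino acids, yielding exactly `19 * length` missense
#' variants. The output order is deterministic — position ascending, then
#' alternate residue alphabetical — so that downstream seeded operations
#' are reproducible. For a 1154-residue kinase this gives the full
#' 21,926-variant saturation space.
#'
#' @param protein A [protein_seq()].
#' @return A tibble with columns `variant`, `position`, `ref_aa`, `alt_aa`.
#' @examples
#' enumerate_saturation(protein_seq("ACD"))
#' @export
enumerate_saturation <- function(protein) {
  stopifnot(inherits(protein, "protein_seq"))
  if (protein$length == 0L) abort("Cannot enumerate an empty sequence.")
  seq_res <- residues_of(protein)
  L <- protein$length
  pos <- rep(seq_len(L), each = 20L)
  ref <- rep(seq_res, each = 20L)
  alt <- rep(AA_CODES, times = L)
  keep <- alt != ref
  tibble(
    variant = format_variant(pos[keep], ref[keep], alt[keep]),
    position = pos[keep], ref_aa = ref[keep], alt_aa = alt[keep]
  )
}

#' Define a domain map
#'
#' A domain map is a set of labelled, non-overlapping, 1-based inclusive
#' residue intervals (e.g. FERM, SH2, pseudokinase, kinase). Intervals
#' are validated and returned sorted by start.
#'
#' @param domain Character labels.
#' @param start,end Integer interval bounds, inclusive.
#' @return A tibble with columns `domain`, `start`, `end`.
#' @export
domain_map <- function(domain, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (length(domain) != length(start) || length(start) != length(end)) {
    abort("`domain`, `start` and `end` must have equal length.")
  }
  if (any(start < 1L) || any(end < start)) {
    abort("Intervals must satisfy 1 <= start <= end.")
  }
  dm <- tibble(domain = as.character(domain), start = start, end = end) |>
    arrange(.data$start)
  if (nrow(dm) > 1L && any(dm$start[-1] <= dm$end[-nrow(dm)])) {
    abort("Domain intervals must be pairwise disjoint.")
  }
  dm
}

#' Illustrative JAK1 domain boundaries (approximate)
#'
#' Approximate boundaries of the human JAK1 FERM, SH2, pseudokinase (PK)
#' and tyrosine kinase (TK) domains, for annotation and display only.
#' These coordinates are rounded from common annotation databases and are
#' not an authoritative domain definition; supply your own
#' [domain_map()] for analyses that depend on exact boundaries.
#'
#' @return A [domain_map()] tibble.
#' @export
jak1_domains_approx <- function() {
  domain_map(
    domain = c("FERM", "SH2", "PK", "TK"),
    start  = c(34L, 439L, 583L, 875L),
    end    = c(420L, 544L, 855L, 1153L)
  )
}

#' Annotate variants with their protein domain
#'
#' Adds a `domain` column giving the label of the interval containing each
#' variant position, or `"linker"` for positions outside every interval.
#'
#' @param variants Tibble with a `position` column (e.g. from
#'   [parse_variants()] or [enumerate_saturation()]).
#' @param map A [domain_map()] tibble.
#' @return `variants` with an added `domain` column.
#' @export
annotate_domains <- function(variants, map) {
  stopifnot(is.data.frame(variants), "position" %in% names(variants))
  idx <- vapply(variants$position, function(p) {
    hit <- which(map$start <= p & p <= map$end)
    if (length(hit) == 0L) NA_integer_ else hit[1]
  }, integer(1))
  variants$domain <- ifelse(is.na(idx), "linker", map$domain[idx])
  variants
}
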