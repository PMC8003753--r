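#' Read a FASTA file into a tibble of sequence records
#'
#' Reads a (wrapped or unwrapped) multi-record FASTA file and validates every
#' record against the alphabet for its type. DNA records may contain
#' `A,C,G,T,N`; protein records the 20 standard amino acids plus `X`.
#' Lowercase letters are normalized to uppercase and input order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param alphabet Either `"dna"` or `"protein"`.
#' @return A tibble with columns `id`, `sequence` and `length` (bp or aa).
#'   The first whitespace-delimited token of each header is the record id.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1", "ACGT"), fa)
#' read_fasta(fa, "dna")
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  stopifnot(file.exists(path))
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("duplicate sequence identifier: '", dup, "'", call. = FALSE)
  }
  seqs <- unname(toupper(as.character(raw)))
  legal <- if (alphabet == "dna") "ACGTN" else "ACDEFGHIKLMNPQRSTVWYX"
  bad <- stringr::str_locate(seqs, paste0("[^", legal, "]"))[, "start"]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    stop("illegal character in record '", ids[i], "' at position ", bad[i],
         call. = FALSE)
  }
  tibble::tibble(id = unname(ids), sequence = unname(seqs),
                 length = nchar(seqs))
}

#' Write sequence records to FASTA
#'
#' @param records A tibble with columns `id` and `sequence` (as produced by
#'   [read_fasta()]).
#' @param path Output file path.
#' @param width Line-wrapping width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  x <- Biostrings::BStringSet(records$sequence)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read CDS features from a GFF3 file
#'
#' Imports a GFF3 annotation, keeps CDS features, validates coordinates
#' against the supplied genomes and returns the features sorted by
#' `(genome_id, start)`. Non-CDS features are dropped with a message giving
#' their count. Coordinates are 1-based inclusive throughout the package
#' (the GFF3 convention).
#'
#' @param path Path to a GFF3 file.
#' @param genomes Tibble of DNA records from [read_fasta()]; `id` must match
#'   the GFF seqid column.
#' @return A tibble with columns `gene_id`, `genome_id`, `start`, `end`,
#'   `strand`, `product`, `locus_tag`.
#' @export
read_gff <- function(path, genomes) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  n_other <- sum(df$type != "CDS")
  if (n_other > 0) {
    message("read_gff: ignoring ", n_other, " non-CDS feature(s)")
  }
  df <- df[df$type == "CDS", , drop = FALSE]
  pick <- function(col, fallback) {
    if (col %in% names(df) && !all(is.na(df[[col]]))) as.character(df[[col]])
    else fallback
  }
  feats <- tibble::tibble(
    gene_id = pick("ID", paste0("cds", seq_len(nrow(df)))),
    genome_id = as.character(df$seqnames),
    start = as.integer(df$start),
    end = as.integer(df$end),
    strand = as.character(df$strand),
    product = pick("product", NA_character_),
    locus_tag = pick("locus_tag", pick("ID", paste0("cds", seq_len(nrow(df)))))
  )
  unknown <- setdiff(feats$genome_id, genomes$id)
  if (length(unknown) > 0) {
    stop("feature references unknown genome: '", unknown[1], "'",
         call. = FALSE)
  }
  glen <- stats::setNames(genomes$length, genomes$id)
  over <- feats$end > glen[feats$genome_id]
  if (any(over)) {
    stop("feature '", feats$gene_id[which(over)[1]],
         "' extends beyond its genome (end > genome length)", call. = FALSE)
  }
  if (any(!feats$strand %in% c("+", "-"))) {
    stop("feature strand must be '+' or '-'", call. = FALSE)
  }
  if (any(feats$start < 1L | feats$start > feats$end)) {
    stop("invalid feature coordinates (need 1 <= start <= end)",
         call. = FALSE)
  }
  dplyr::arrange(feats, .data$genome_id, .data$start)
}

#' Write gene features as GFF3
#'
#' @param features Feature tibble as returned by [read_gff()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(features, path) {
  lines <- c("##gff-version 3", sprintf(
    "%s\tlantiscan\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;locus_tag=%s%s",
    features$genome_id, features$start, features$end, features$strand,
    features$gene_id, features$locus_tag,
    ifelse(is.na(features$product), "",
           paste0(";product=", features$product))
  ))
  writeLines(lines, path)
  invisible(path)
}

# Bacterial (table 11) genetic code; codons with N translate to X.
.genetic_code_11 <- function() Biostrings::getGeneticCode("11")

#' Derive a proteome from an annotated genome
#'
#' Translates every CDS feature with the bacterial genetic code (translation
#' table 11). Minus-strand CDS are reverse-complemented before translation;
#' a single trailing stop codon is removed; ambiguous codons containing `N`
#' translate to `X`.
#'
#' @param genome One row of a DNA record tibble ([read_fasta()]).
#' @param features Feature tibble for that genome ([read_gff()]).
#' @return A tibble with columns `id` (the locus_tag), `sequence`, `length`
#'   and `source_gene`.
#' @export
extract_proteome <- function(genome, features) {
  stopifnot(nrow(genome) == 1)
  feats <- features[features$genome_id == genome$id, , drop = FALSE]
  if (nrow(feats) == 0) {
    return(tibble::tibble(id = character(), sequence = character(),
                          length = integer(), source_gene = character()))
  }
  bad_len <- (feats$end - feats$start + 1L) %% 3L != 0L
  if (any(bad_len)) {
    stop("CDS length of gene '", feats$gene_id[which(bad_len)[1]],
         "' is not divisible by 3", call. = FALSE)
  }
  cds <- substring(genome$sequence, feats$start, feats$end)
  minus <- feats$strand == "-"
  if (any(minus)) {
    cds[minus] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(cds[minus])))
  }
  # no.init.codon: translate the first codon literally rather than forcing
  # an initiator methionine, so translation round-trips back-translated
  # sequences exactly
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(cds),
    genetic.code = .genetic_code_11(),
    if.fuzzy.codon = "solve", no.init.codon = TRUE
  ))
  aa <- sub("\\*$", "", aa)
  internal <- grepl("\\*", aa)
  if (any(internal)) {
    stop("internal stop codon in gene '",
         feats$gene_id[which(internal)[1]], "'", call. = FALSE)
  }
  tibble::tibble(id = feats$locus_tag, sequence = aa, length = nchar(aa),
                 source_gene = feats$gene_id)
}
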