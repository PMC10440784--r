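# Record-level transforms the converters are built from.

IUPAC_FROM <- "ACGTUacgtuRYSWKMryswkmBDHVbdhvNn"
IUPAC_TO   <- "TGCAAtgcaaYRSWMKyrswmkVHDBvhdbNn"

#' Reverse-complement a nucleotide sequence
#'
#' IUPAC ambiguity codes are complemented; characters outside the IUPAC
#' alphabet are preserved unchanged. The operation is an involution.
#'
#' @param sequence Character vector of sequences.
#' @return Character vector of reverse-complemented sequences.
#' @examples
#' reverse_complement("AACG")  # "CGTT"
#' @export
reverse_complement <- function(sequence) {
  comp <- chartr(IUPAC_FROM, IUPAC_TO, sequence)
  vapply(comp, function(s) {
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Decode / encode Phred quality strings
#'
#' `phred_decode()` maps each character of a quality string to
#' `code - offset`; `phred_encode()` is its inverse. The default offset of
#' 33 is the Sanger (Phred+33) convention used by modern FASTQ.
#'
#' @param qual Quality string (one element).
#' @param scores Integer vector of Phred scores in `[0, 93]`.
#' @param offset ASCII offset; 33 unless you really have legacy data.
#' @return `phred_decode()` an integer vector; `phred_encode()` a string.
#' @export
phred_decode <- function(qual, offset = 33L) {
  if (nchar(qual) == 0L) return(integer())
  codes <- utf8ToInt(qual)
  if (any(codes < offset))
    bc_stop("bc_phred_error",
            sprintf("quality character code %d below offset %d; wrong Phred offset?",
                    min(codes), offset))
  codes - as.integer(offset)
}

#' @rdname phred_decode
#' @export
phred_encode <- function(scores, offset = 33L) {
  if (length(scores) == 0L) return("")
  scores <- as.integer(scores)
  if (any(scores < 0L | scores > 93L))
    bc_stop("bc_phred_error", "Phred scores must lie in [0, 93]")
  intToUtf8(scores + as.integer(offset))
}

#' Extract the sequencing read from a SAM record
#'
#' Returns `NULL` for records without a stored sequence and for secondary
#' (flag 0x100) or supplementary (0x800) alignments, so each read appears
#' at most once in an export. When the reverse-strand bit (0x10) is set,
#' the original read orientation is restored: the sequence is
#' reverse-complemented and the quality reversed.
#'
#' @param record A [sam_record()].
#' @return A [seq_record()] or `NULL`.
#' @export
sam_to_seqrecord <- function(record) {
  if (record$seq == "*") return(NULL)
  if (bitwAnd(record$flag, 0x100L) != 0L || bitwAnd(record$flag, 0x800L) != 0L)
    return(NULL)
  seq <- record$seq
  qual <- if (record$qual == "*") NULL else phred_decode(record$qual)
  if (bitwAnd(record$flag, 0x10L) != 0L) {
    seq <- reverse_complement(seq)
    if (!is.null(qual)) qual <- rev(qual)
  }
  seq_record(record$qname, seq, quality = qual)
}

#' Convert a GFF3 feature row to a genomic interval
#'
#' GFF3 uses 1-based inclusive coordinates; BED-convention intervals are
#' 0-based half-open, so `start = gff_start - 1` and `end = gff_end`.
#' The interval name is the feature's `ID` attribute when present.
#'
#' @param feature A parsed GFF3 feature row (as yielded by
#'   [parse_records()] with `format = "gff3"`).
#' @return A [genomic_interval()].
#' @export
gff3_to_interval <- function(feature) {
  if (is.na(feature$start) || feature$start < 1L)
    bc_stop("bc_coordinate_error",
            sprintf("GFF3 start must be >= 1 (got %s)", feature$start))
  if (is.na(feature$end) || feature$end < feature$start)
    bc_stop("bc_coordinate_error",
            sprintf("GFF3 end (%s) must be >= start (%s)", feature$end, feature$start))
  name <- feature$attributes[["ID"]]
  if (is.null(name) || !nzchar(name)) name <- "."
  strand <- feature$strand
  if (!strand %in% c("+", "-")) strand <- "."
  genomic_interval(feature$seqid, feature$start - 1L, feature$end,
                   name = name, score = feature$score, strand = strand)
}

#' Convert a VCF data row to a genomic interval
#'
#' The interval spans the reference allele: `[POS - 1, POS - 1 + nchar(REF))`
#' in 0-based half-open coordinates. Name is the variant ID (or "."), score
#' the QUAL column; VCF rows carry no strand.
#'
#' @param variant A parsed VCF row (as yielded by [parse_records()] with
#'   `format = "vcf"`).
#' @return A [genomic_interval()].
#' @export
variant_to_interval <- function(variant) {
  pos <- variant$pos
  if (is.na(pos))
    bc_stop("bc_parse_error", sprintf("non-integer POS in VCF row on %s", variant$chrom))
  genomic_interval(variant$chrom, pos - 1L, pos - 1L + nchar(variant$ref),
                   name = variant$id, score = variant$qual, strand = ".")
}

# Standard genetic code, frame 1; incomplete trailing codons are dropped,
# codons containing non-ACGT characters translate to 'X'.
GENETIC_CODE_TABLE <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

#' Translate a DNA sequence (frame 1, standard code)
#'
#' @param sequence DNA string; U is treated as T, case-insensitive.
#' @return Amino-acid string; trailing partial codons are dropped.
#' @export
translate_dna <- function(sequence) {
  s <- chartr("u", "t", tolower(sequence))
  s <- toupper(s)
  n <- nchar(s) %/% 3L
  if (n == 0L) return("")
  codons <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- GENETIC_CODE_TABLE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
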