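#' Construct a transcript model
#'
#' Strand-aware exon structure over a provided genomic sequence, with CDS
#' bounds in transcript (spliced cDNA) coordinates. All genomic
#' coordinates are 1-based inclusive, relative to `seq_start` (the
#' genomic coordinate of the first base of `genomic_sequence`).
#'
#' @param id transcript name.
#' @param strand `"+"` or `"-"`.
#' @param exons data frame with `start`, `end` columns (genomic, 1-based
#'   inclusive), sorted by genomic position, non-overlapping.
#' @param cds_start,cds_end CDS bounds in transcript coordinates (1-based
#'   positions in the spliced cDNA).
#' @param genomic_sequence character string of A/C/G/T covering the locus.
#' @param seq_start genomic coordinate of `genomic_sequence[1]`.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(id, strand, exons, cds_start, cds_end,
                             genomic_sequence, seq_start = 1L) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as.data.frame(exons)
  stopifnot(all(c("start", "end") %in% names(exons)), nrow(exons) >= 1)
  if (is.unsorted(exons$start, strictly = TRUE) ||
      any(exons$end < exons$start)) {
    stop("exons must be sorted by genomic position and well-formed")
  }
  if (nrow(exons) > 1L && any(exons$start[-1L] <= exons$end[-nrow(exons)])) {
    stop("exons must be non-overlapping")
  }
  seq_end <- seq_start + nchar(genomic_sequence) - 1L
  if (min(exons$start) < seq_start || max(exons$end) > seq_end) {
    stop("exon outside the provided genomic sequence")
  }
  spliced_len <- sum(exons$end - exons$start + 1L)
  stopifnot(cds_start >= 1, cds_end <= spliced_len,
            cds_end - cds_start + 1L >= 3L)
  structure(list(id = id, strand = strand, exons = exons,
                 cds_start = as.integer(cds_start),
                 cds_end = as.integer(cds_end),
                 genomic_sequence = toupper(genomic_sequence),
                 seq_start = as.integer(seq_start)),
            class = "transcript_model")
}

exon_substrings <- function(t) {
  substring(t$genomic_sequence,
            t$exons$start - t$seq_start + 1L,
            t$exons$end - t$seq_start + 1L)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Spliced cDNA of a transcript model
#'
#' Concatenates the exon sequences in transcript order; for minus-strand
#' transcripts this is the reverse complement of the genomic exon
#' concatenation.
#'
#' @param t a [transcript_model].
#' @return Character string, 5'->3' cDNA.
#' @export
spliced_cdna <- function(t) {
  plus <- paste(exon_substrings(t), collapse = "")
  if (t$strand == "+") plus else revcomp(plus)
}

# per-exonic-base genomic positions in genomic order
exonic_positions <- function(t) {
  unlist(mapply(seq.int, t$exons$start, t$exons$end, SIMPLIFY = FALSE))
}

# transcript coordinate of a genomic exonic position (strand converted)
transcript_coord <- function(t, gpos) {
  ep <- exonic_positions(t)
  i <- match(gpos, ep)
  if (t$strand == "+") i else length(ep) - i + 1L
}

#' Apply a genomic deletion at or near an exon boundary to the spliced cDNA
#'
#' Models the empirically observed splice outcome for deletions touching
#' an exon's terminal base(s): splicing is preserved and the donor (or
#' acceptor) shifts to recruit the adjacent base, so the spliced cDNA
#' loses exactly the deleted exonic base count. Deletions fully inside an
#' exon behave as ordinary exonic deletions; fully intronic deletions
#' leave the cDNA unchanged (with a notice); a deletion spanning a whole
#' exon is unsupported.
#'
#' @param t a [transcript_model].
#' @param del_start,del_end genomic deletion interval, 1-based inclusive;
#'   `del_end < del_start` encodes a zero-length deletion (identity).
#' @return List with `cdna` (edited spliced cDNA), `hgvs_c`
#'   (`c.<pos>del<base>` style, transcript coordinates and strand),
#'   `n_deleted` (exonic bases removed) and `deleted_tx_pos` (transcript
#'   positions removed).
#' @export
apply_boundary_deletion <- function(t, del_start, del_end) {
  ref_cdna <- spliced_cdna(t)
  if (del_end < del_start) { # zero-length deletion: identity
    return(list(cdna = ref_cdna, hgvs_c = "c.=", n_deleted = 0L,
                deleted_tx_pos = integer()))
  }
  hit <- t$exons$start <= del_end & t$exons$end >= del_start
  if (!any(hit)) {
    message("deletion is fully intronic; spliced cDNA unchanged")
    return(list(cdna = ref_cdna, hgvs_c = "c.=", n_deleted = 0L,
                deleted_tx_pos = integer()))
  }
  if (sum(hit) > 1L) {
    stop("deletion overlaps more than one exon; unsupported")
  }
  ex <- t$exons[hit, ]
  if (del_start <= ex$start && del_end >= ex$end) {
    stop("deletion spans a whole exon; unsupported")
  }
  gpos <- seq.int(max(del_start, ex$start), min(del_end, ex$end))
  tx <- sort(vapply(gpos, function(p) transcript_coord(t, p), integer(1)))
  bases_cdna <- substring(ref_cdna, tx, tx)
  edited <- paste0(substr(ref_cdna, 1L, tx[1] - 1L),
                   substr(ref_cdna, tx[length(tx)] + 1L, nchar(ref_cdna)))
  hgvs <- if (length(tx) == 1L) {
    sprintf("c.%ddel%s", tx, bases_cdna)
  } else {
    sprintf("c.%d_%ddel%s", tx[1], tx[length(tx)],
            paste(bases_cdna, collapse = ""))
  }
  list(cdna = edited, hgvs_c = hgvs, n_deleted = length(tx),
       deleted_tx_pos = tx)
}

translate_dna <- function(x) {
  x <- substr(x, 1L, nchar(x) - nchar(x) %% 3L)
  if (!nchar(x)) return("")
  suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(x),
                          if.fuzzy.codon = "X")))
}

#' Protein consequence of an edited cDNA
#'
#' Translates the reference CDS and the edited sequence (from the CDS
#' start through the end of the edited cDNA, so a frameshift reads into
#' the former 3' UTR), finds the first divergent residue and classifies
#' the change. A deletion whose length is a multiple of 3 is in-frame;
#' otherwise the change is a frameshift whose `stop_offset` counts the
#' first divergent residue as 1.
#'
#' @param original_cdna,edited_cdna spliced cDNA before/after the edit.
#' @param cds_start,cds_end CDS bounds (transcript coordinates) in the
#'   *original* cDNA.
#' @return An object of class `protein_consequence`: list with `kind`
#'   (`synonymous_or_identity`, `inframe_deletion`, `stop_gained` or
#'   `frameshift`), `first_affected_residue`, `original_residue`,
#'   `new_residue`, `stop_offset` (integer or `NA` = not found) and
#'   `hgvs_p`.
#' @examples
#' translate_consequence("ATGAAGCTGACCTAA", "ATGAGCTGACCTAA", 1, 15)
#' @export
translate_consequence <- function(original_cdna, edited_cdna,
                                  cds_start, cds_end) {
  if (nchar(edited_cdna) < cds_start + 2L) {
    stop("edited sequence shorter than the start codon")
  }
  ref_cds <- substr(original_cdna, cds_start, cds_end)
  ref_prot <- translate_dna(ref_cds)
  aa <- strsplit(ref_prot, "")[[1]]
  if ("*" %in% aa[-length(aa)]) {
    stop("reference CDS contains an internal stop codon")
  }
  del_len <- nchar(original_cdna) - nchar(edited_cdna)
  # read the edited frame through to the end of the transcript
  alt_prot <- translate_dna(substr(edited_cdna, cds_start,
                                   nchar(edited_cdna)))
  ref_trim <- sub("\\*$", "", ref_prot)
  alt_stop <- regexpr("*", alt_prot, fixed = TRUE)
  alt_trim <- if (alt_stop > 0) substr(alt_prot, 1L, alt_stop - 1L) else alt_prot

  if (identical(ref_trim, alt_trim)) {
    return(new_protein_consequence("synonymous_or_identity", NA_integer_,
                                   NA_character_, NA_character_, NA_integer_))
  }
  ra <- strsplit(ref_trim, "")[[1]]
  ea <- strsplit(alt_trim, "")[[1]]
  n <- min(length(ra), length(ea))
  div <- which(ra[seq_len(n)] != ea[seq_len(n)])
  i <- if (length(div)) div[1] else n + 1L
  orig_res <- if (i <= length(ra)) ra[i] else "*"
  new_res <- if (i <= length(ea)) ea[i] else "*"

  if (new_res == "*") {
    # the first divergent residue is itself a stop: a nonsense outcome,
    # whatever the deletion phase
    return(new_protein_consequence("stop_gained", i, orig_res, "*",
                                   NA_integer_))
  }
  if (del_len %% 3L != 0L) {
    # frameshift: offset of the first stop in the new frame, counting the
    # divergent residue as 1 (always >= 2 here since residue i is not a
    # stop)
    stop_offset <- if (alt_stop > 0 && alt_stop >= i) {
      as.integer(alt_stop - i + 1L)
    } else NA_integer_
    return(new_protein_consequence("frameshift", i, orig_res, new_res,
                                   stop_offset))
  }
  new_protein_consequence("inframe_deletion", i, orig_res, new_res,
                          NA_integer_)
}

new_protein_consequence <- function(kind, pos, orig, new, stop_offset) {
  hgvs <- switch(kind,
    synonymous_or_identity = "p.=",
    frameshift = sprintf("p.%s%d%sfs*%s", orig, pos, new,
                         if (is.na(stop_offset)) "?" else stop_offset),
    stop_gained = sprintf("p.%s%d*", orig, pos),
    inframe_deletion = sprintf("p.%s%ddel", orig, pos)
  )
  structure(list(kind = kind, first_affected_residue = pos,
                 original_residue = orig, new_residue = new,
                 stop_offset = stop_offset, hgvs_p = hgvs),
            class = "protein_consequence")
}

#' @export
print.protein_consequence <- function(x, ...) {
  cat(x$hgvs_p, sprintf("(%s)", x$kind), "\n")
  invisible(x)
}

#' Predict the protein consequence of a genomic deletion on a transcript
#'
#' Convenience wrapper: [apply_boundary_deletion()] followed by
#' [translate_consequence()]; for frameshifts the CDS end used for the
#' edited sequence extends to the transcript end automatically.
#'
#' @inheritParams apply_boundary_deletion
#' @return List with `hgvs_c`, the `protein_consequence`, and the edited
#'   cDNA.
#' @export
predict_deletion_consequence <- function(t, del_start, del_end) {
  ed <- apply_boundary_deletion(t, del_start, del_end)
  cons <- translate_consequence(spliced_cdna(t), ed$cdna,
                                t$cds_start, t$cds_end)
  list(hgvs_c = ed$hgvs_c, consequence = cons, cdna = ed$cdna,
       n_deleted = ed$n_deleted)
}

#' Read a transcript model from an exon-table TSV plus FASTA
#'
#' The TSV holds one `exon` row per exon (`type`, `start`, `end`) and one
#' `cds` row with transcript-space CDS bounds; `strand` and `id` are
#' taken from the first row's `strand`/`transcript` columns. The FASTA
#' provides the locus sequence (first record; its header may carry
#' `start=<pos>` to set the genomic offset).
#'
#' @param tsv path to the exon table.
#' @param fasta path to the locus FASTA.
#' @return A [transcript_model].
#' @export
read_transcript_model <- function(tsv, fasta) {
  tab <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  stopifnot(all(c("type", "start", "end", "strand", "transcript") %in%
                  names(tab)))
  ex <- tab[tab$type == "exon", ]
  cds <- tab[tab$type == "cds", ]
  if (nrow(cds) != 1L) stop("transcript table must have exactly one cds row")
  seqs <- Biostrings::readDNAStringSet(fasta)
  hdr <- names(seqs)[1]
  m <- regmatches(hdr, regexec("start=([0-9]+)", hdr))[[1]]
  seq_start <- if (length(m) == 2L) as.integer(m[2]) else 1L
  transcript_model(
    id = tab$transcript[1], strand = tab$strand[1],
    exons = ex[order(ex$start), c("start", "end")],
    cds_start = cds$start, cds_end = cds$end,
    genomic_sequence = as.character(seqs[[1]]),
    seq_start = seq_start
  )
}
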