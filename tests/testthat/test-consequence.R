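# two-exon toy used throughout: exon1 1..12, intron 13..20, exon2 21..32
toy_plus <- function(seq = NULL) {
  if (is.null(seq)) {
    set.seed(9)
    seq <- random_dna(32)
  }
  transcript_model("toy+", "+",
                   exons = data.frame(start = c(1, 21), end = c(12, 32)),
                   cds_start = 1, cds_end = 24,
                   genomic_sequence = seq)
}

revcomp_str <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

test_that("spliced cDNA concatenates exons and honors strand", {
  one <- transcript_model("t1", "+", data.frame(start = 3, end = 14),
                          cds_start = 1, cds_end = 12,
                          genomic_sequence = "GGATGAAACCCGGGTT")
  expect_equal(spliced_cdna(one), substr("GGATGAAACCCGGGTT", 3, 14))

  g <- "ATGAAGCTGACCTAAGGGGGCCCTTTAAACCC"
  tp <- transcript_model("t2", "+", data.frame(start = c(1, 21),
                                               end = c(12, 32)),
                         cds_start = 1, cds_end = 24, genomic_sequence = g)
  plus_cdna <- paste0(substr(g, 1, 12), substr(g, 21, 32))
  expect_equal(spliced_cdna(tp), plus_cdna)

  tm <- transcript_model("t3", "-", data.frame(start = c(1, 21),
                                               end = c(12, 32)),
                         cds_start = 1, cds_end = 24, genomic_sequence = g)
  expect_equal(spliced_cdna(tm), revcomp_str(plus_cdna))
})

test_that("malformed exon structures are rejected", {
  expect_error(
    transcript_model("bad", "+", data.frame(start = c(21, 1),
                                            end = c(32, 12)),
                     1, 24, random_dna(32)),
    "sorted")
  expect_error(
    transcript_model("bad", "+", data.frame(start = c(1, 10),
                                            end = c(12, 20)),
                     1, 12, random_dna(32)),
    "non-overlapping")
  expect_error(
    transcript_model("bad", "+", data.frame(start = 1, end = 40),
                     1, 12, random_dna(32)),
    "outside")
})

test_that("deleting the terminal exonic base shifts the donor by one base", {
  t <- toy_plus()
  ref <- spliced_cdna(t)
  # last base of exon 1 (genomic position 12, transcript position 12)
  ed <- apply_boundary_deletion(t, 12, 12)
  expect_equal(nchar(ed$cdna), nchar(ref) - 1L)
  expect_equal(ed$cdna, paste0(substr(ref, 1, 11), substr(ref, 13, 24)))
  expect_equal(ed$hgvs_c, sprintf("c.12del%s", substr(ref, 12, 12)))

  # zero-length deletion: identity
  id <- apply_boundary_deletion(t, 12, 11)
  expect_equal(id$cdna, ref)
  expect_equal(id$n_deleted, 0L)

  # fully intronic deletion: identity with a notice
  expect_message(intr <- apply_boundary_deletion(t, 15, 16), "intronic")
  expect_equal(intr$cdna, ref)

  # whole-exon deletion unsupported
  expect_error(apply_boundary_deletion(t, 20, 33), "whole exon")
  expect_error(apply_boundary_deletion(t, 5, 25), "more than one exon")
})

test_that("a genomic delC on a minus-strand transcript is a cDNA delG", {
  # genomic: exon2 ends ...C at its last base; on the minus strand the
  # transcript reads exon2 first, so that C is a transcript G
  g <- paste0(strrep("A", 4), "TTACGGCATGCA", strrep("T", 8),
              "CCATTTGGGCAC")
  # exons 5..16 and 25..36 on the genome; minus strand
  t <- transcript_model("toy-", "-",
                        exons = data.frame(start = c(5, 25),
                                           end = c(16, 36)),
                        cds_start = 1, cds_end = 24,
                        genomic_sequence = g)
  # delete the genomic C at position 25 (first base of the genomic-order
  # second exon = last base of the transcript's first exon region)
  expect_equal(substr(g, 25, 25), "C")
  ed <- apply_boundary_deletion(t, 25, 25)
  expect_equal(ed$n_deleted, 1L)
  expect_match(ed$hgvs_c, "delG$")
  expect_equal(nchar(ed$cdna), 23L)
})

test_that("frameshift translation matches the worked example p.K2Sfs*2", {
  cons <- translate_consequence("ATGAAGCTGACCTAA", "ATGAGCTGACCTAA", 1, 15)
  expect_equal(cons$kind, "frameshift")
  expect_equal(cons$first_affected_residue, 2L)
  expect_equal(cons$original_residue, "K")
  expect_equal(cons$new_residue, "S")
  expect_equal(cons$stop_offset, 2L)
  expect_equal(cons$hgvs_p, "p.K2Sfs*2")
})

test_that("whole-codon deletions are in-frame; no edit is identity", {
  inframe <- translate_consequence("ATGAAGCTGACCTAA", "ATGCTGACCTAA", 1, 15)
  expect_equal(inframe$kind, "inframe_deletion")
  expect_equal(inframe$first_affected_residue, 2L)

  ident <- translate_consequence("ATGAAGCTGACCTAA", "ATGAAGCTGACCTAA", 1, 15)
  expect_equal(ident$kind, "synonymous_or_identity")

  expect_error(translate_consequence("ATGAAGTAA", "AT", 1, 9), "start codon")
})

test_that("consequences are invariant under strand representation", {
  set.seed(21)
  for (i in 1:20) {
    tx <- random_cds_transcript(n_codons = 12, utr5 = 0, utr3 = 6)
    L <- nchar(tx$cdna)
    g_plus <- tx$cdna
    plus <- transcript_model("p", "+", data.frame(start = 1, end = L),
                             tx$cds_start, tx$cds_end,
                             genomic_sequence = g_plus)
    minus <- transcript_model("m", "-", data.frame(start = 1, end = L),
                              tx$cds_start, tx$cds_end,
                              genomic_sequence = revcomp_str(g_plus))
    # delete the same transcript base through both encodings
    tx_pos <- sample(seq(tx$cds_start + 3, tx$cds_end - 6), 1)
    res_p <- predict_deletion_consequence(plus, tx_pos, tx_pos)
    g_min <- L - tx_pos + 1
    res_m <- predict_deletion_consequence(minus, g_min, g_min)
    expect_equal(res_p$consequence, res_m$consequence)
    expect_equal(res_p$hgvs_c, res_m$hgvs_c)
  }
})

test_that("random 1-bp CDS deletions agree with the full-translation oracle", {
  set.seed(33)
  for (i in 1:100) {
    tx <- random_cds_transcript(n_codons = sample(5:25, 1))
    del <- sample(seq(tx$cds_start, tx$cds_end - 3), 1)
    edited <- paste0(substr(tx$cdna, 1, del - 1),
                     substr(tx$cdna, del + 1, nchar(tx$cdna)))
    got <- translate_consequence(tx$cdna, edited, tx$cds_start, tx$cds_end)
    want <- oracle_consequence(tx$cdna, edited, tx$cds_start, tx$cds_end)
    expect_equal(got$kind, want$kind)
    if (want$kind == "frameshift") {
      expect_equal(got$first_affected_residue, want$pos)
      expect_equal(got$original_residue, want$orig)
      expect_equal(got$new_residue, want$new)
      expect_equal(got$stop_offset, want$stop_offset)
    }
  }
})

test_that("frameshift occurs exactly when the deleted length is not a
           multiple of three", {
  tx <- random_cds_transcript(n_codons = 15, utr5 = 3, utr3 = 12)
  for (start in seq(tx$cds_start + 3, tx$cds_start + 20)) {
    for (len in 1:4) {
      edited <- paste0(substr(tx$cdna, 1, start - 1),
                       substr(tx$cdna, start + len, nchar(tx$cdna)))
      got <- translate_consequence(tx$cdna, edited, tx$cds_start,
                                   tx$cds_end)
      if (len %% 3 != 0) {
        # phase-breaking deletions shift the frame; the only escapes are
        # a coincidentally identical protein or an immediate stop
        expect_true(got$kind %in% c("frameshift", "stop_gained",
                                    "synonymous_or_identity"))
        if (got$kind == "frameshift") {
          expect_true(is.na(got$stop_offset) || got$stop_offset >= 2)
        }
      } else {
        expect_false(got$kind == "frameshift")
      }
    }
  }
})

test_that("transcript models round-trip through the TSV+FASTA reader", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".fa")
  g <- "ATGAAGCTGACCTAAGGGGGCCCTTTAAACCC"
  writeLines(c("type\tstart\tend\tstrand\ttranscript",
               "exon\t1\t12\t+\ttx1",
               "exon\t21\t32\t+\ttx1",
               "cds\t1\t24\t+\ttx1"), tsv)
  writeLines(c(">locus start=1", g), fa)
  t <- read_transcript_model(tsv, fa)
  expect_equal(t$id, "tx1")
  expect_equal(spliced_cdna(t), paste0(substr(g, 1, 12), substr(g, 21, 32)))
})
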