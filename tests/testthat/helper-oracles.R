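# Independent oracles and fixture builders shared across test files.

# Brute-force ROH oracle: enumerate every window of consecutive sites,
# test the run rule directly, keep the non-extendable windows. Written
# against the rule statement, independent of the block-splitting
# implementation in detect_roh().
roh_oracle <- function(pos, class, min_run = 4) {
  empty <- data.frame(start = integer(), end = integer(),
                      n_snvs = integer())
  n <- length(pos)
  if (!n) return(empty)
  hom <- class == "HQ_HOM"
  het <- class == "HET"
  H0 <- c(0, cumsum(het))   # hets among sites 1..i = H0[i+1]
  N0 <- c(0, cumsum(hom))
  no_het <- function(i, j) H0[j + 1] - H0[i] == 0
  n_hom <- function(i, j) N0[j + 1] - N0[i]
  idx <- which(hom)
  out <- list()
  for (i in idx) {
    for (j in idx[idx >= i]) {
      if (!no_het(i, j) || n_hom(i, j) < min_run) next
      # maximal: no hom k < i (or k > j) reachable without crossing a het
      left_ext <- any(vapply(idx[idx < i], function(k) no_het(k, j), TRUE))
      right_ext <- any(vapply(idx[idx > j], function(k) no_het(i, k), TRUE))
      if (!left_ext && !right_ext) {
        out[[length(out) + 1]] <- data.frame(start = pos[i], end = pos[j],
                                             n_snvs = n_hom(i, j))
      }
    }
  }
  if (!length(out)) return(empty)
  res <- unique(do.call(rbind, out))
  res[order(res$start), , drop = FALSE]
}

random_classified_chromosome <- function(max_sites = 200) {
  n <- sample(0:max_sites, 1)
  pos <- sort(sample.int(1e6, n))
  cls <- sample(c("HQ_HOM", "HET", "LOW_QUALITY", "MISSING"), n,
                replace = TRUE, prob = c(0.5, 0.2, 0.2, 0.1))
  list(pos = pos, class = cls)
}

# Full-translation diff oracle for protein consequences, built on
# seqinr's translation (independent of the Biostrings-based module).
oracle_consequence <- function(original_cdna, edited_cdna, cds_start,
                               cds_end) {
  tr <- function(x) {
    x <- substr(x, 1, nchar(x) - nchar(x) %% 3)
    if (!nchar(x)) return(character())
    seqinr::translate(seqinr::s2c(x))
  }
  ref <- tr(substr(original_cdna, cds_start, cds_end))
  alt <- tr(substr(edited_cdna, cds_start, nchar(edited_cdna)))
  trim <- function(aa) {
    s <- which(aa == "*")
    if (length(s)) aa[seq_len(s[1] - 1)] else aa
  }
  ref_t <- trim(ref)
  alt_stop <- which(alt == "*")
  alt_t <- trim(alt)
  del_len <- nchar(original_cdna) - nchar(edited_cdna)
  if (identical(ref_t, alt_t)) {
    return(list(kind = "synonymous_or_identity"))
  }
  m <- min(length(ref_t), length(alt_t))
  div <- which(ref_t[seq_len(m)] != alt_t[seq_len(m)])
  i <- if (length(div)) div[1] else m + 1
  orig <- if (i <= length(ref_t)) ref_t[i] else "*"
  new <- if (i <= length(alt_t)) alt_t[i] else "*"
  if (new == "*") {
    list(kind = "stop_gained", pos = i, orig = orig)
  } else if (del_len %% 3 != 0) {
    so <- if (length(alt_stop) && alt_stop[1] >= i) alt_stop[1] - i + 1
          else NA_integer_
    list(kind = "frameshift", pos = i, orig = orig, new = new,
         stop_offset = as.integer(so))
  } else {
    list(kind = "inframe_deletion", pos = i, orig = orig)
  }
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random CDS with a clean reading frame: ATG + random non-stop codons +
# stop, embedded in optional UTRs
random_cds_transcript <- function(n_codons = 20, utr5 = 6, utr3 = 9) {
  non_stop <- setdiff(
    apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                      c("A", "C", "G", "T")), 1, paste, collapse = ""),
    c("TAA", "TAG", "TGA"))
  cds <- paste0("ATG",
                paste(sample(non_stop, n_codons - 2, replace = TRUE),
                      collapse = ""),
                sample(c("TAA", "TAG", "TGA"), 1))
  list(cdna = paste0(random_dna(utr5), cds, random_dna(utr3)),
       cds_start = utr5 + 1, cds_end = utr5 + nchar(cds))
}

# small variant set with randomized genotypes for round-trip tests
random_variant_set <- function(n_sites = 12, samples = c("s1", "s2")) {
  sites <- data.frame(
    chrom = sort(sample(c("1", "2"), n_sites, replace = TRUE)),
    pos = 0L, id = paste0("v", seq_len(n_sites)),
    ref = sample(c("A", "C", "G", "T"), n_sites, replace = TRUE),
    alt = "T", stringsAsFactors = FALSE)
  sites$alt <- ifelse(sites$ref == "T", "G", "T")
  for (ch in unique(sites$chrom)) {
    i <- sites$chrom == ch
    sites$pos[i] <- sort(sample.int(1e6, sum(i)))
  }
  pick <- function(n) sample(c("0/0", "0/1", "1/1", NA), n, replace = TRUE,
                             prob = c(0.4, 0.25, 0.25, 0.1))
  gt <- matrix(pick(n_sites * length(samples)), n_sites,
               dimnames = list(NULL, samples))
  gq <- matrix(ifelse(is.na(gt), NA, sample(0:99, length(gt), TRUE)),
               n_sites, dimnames = list(NULL, samples))
  ad <- matrix(ifelse(is.na(gt), NA,
                      paste(sample(0:30, length(gt), TRUE),
                            sample(0:30, length(gt), TRUE), sep = ",")),
               n_sites, dimnames = list(NULL, samples))
  variant_set(sites, gt, gq, ad)
}

quartet_pedigree <- function() {
  pedigree(
    id = c("father", "mother", "II.1", "II.2"),
    sex = c("male", "female", "male", "male"),
    affected = c(FALSE, FALSE, TRUE, TRUE),
    father = c(NA, NA, "father", "father"),
    mother = c(NA, NA, "mother", "mother")
  )
}
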