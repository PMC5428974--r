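#' Per-variant annotation bundle
#'
#' Population and functional annotations consumed by the filter cascade:
#' per-database allele frequencies and control heterozygote/homozygote
#' counts, deleteriousness prediction labels (e.g. SIFT, PolyPhen2), a
#' conservation score (GERP-like), a clinical phenotype-match flag and an
#' optional known disease link. Prediction scores are consumed as inputs,
#' never computed here.
#'
#' @param frequency named numeric vector of allele frequencies in [0, 1],
#'   one per database.
#' @param het_count named numeric vector of control heterozygote counts.
#' @param hom_count named numeric vector of control homozygote counts.
#' @param predictions named character vector of tool -> label (e.g.
#'   `c(SIFT = "tolerated")`).
#' @param conservation conservation score, or `NULL` if unknown.
#' @param phenotype_match `"yes"`, `"no"` or `"unknown"`; a clinical
#'   judgment supplied as input, not computed.
#' @param disease_link optional free-text known disease association.
#' @return A list of class `annotation_bundle`.
#' @export
annotation_bundle <- function(frequency = numeric(), het_count = numeric(),
                              hom_count = numeric(), predictions = character(),
                              conservation = NULL,
                              phenotype_match = "unknown",
                              disease_link = NULL) {
  frequency <- frequency[!is.na(frequency)]
  het_count <- het_count[!is.na(het_count)]
  hom_count <- hom_count[!is.na(hom_count)]
  if (any(frequency < 0 | frequency > 1)) {
    stop("allele frequencies must lie in [0, 1]")
  }
  if (any(c(het_count, hom_count) < 0)) stop("control counts must be >= 0")
  stopifnot(phenotype_match %in% c("yes", "no", "unknown"))
  structure(list(frequency = frequency, het_count = het_count,
                 hom_count = hom_count, predictions = predictions,
                 conservation = conservation,
                 phenotype_match = phenotype_match,
                 disease_link = disease_link),
            class = "annotation_bundle")
}

#' Parameters for the recessive filter cascade
#'
#' @param freq_cutoff per-database allele-frequency (prevalence) cutoff;
#'   a variant exceeding it in any database fails. Default 0.5%.
#' @param benign_conservation_cutoff conservation score below which, in
#'   the absence of any damaging-class prediction, a variant is ranked
#'   unlikely disease-causing.
#' @param damaging_labels prediction labels counted as a damaging call.
#' @param benign_labels prediction labels counted as benign (intermediate
#'   labels such as "possibly damaging" are neither).
#' @param on_missing_parent how a missing parental genotype is handled in
#'   segregation: `"fail"` (default; recorded as `missing_data`, not
#'   `fails_segregation`) or `"ignore"`.
#' @return A list of class `prioritization_params`.
#' @export
prioritization_params <- function(freq_cutoff = 0.005,
                                  benign_conservation_cutoff = 2.0,
                                  damaging_labels = c("damaging",
                                                      "probably damaging",
                                                      "probably_damaging",
                                                      "deleterious",
                                                      "disease causing"),
                                  benign_labels = c("tolerated", "benign"),
                                  on_missing_parent = c("fail", "ignore")) {
  structure(list(freq_cutoff = freq_cutoff,
                 benign_conservation_cutoff = benign_conservation_cutoff,
                 damaging_labels = tolower(damaging_labels),
                 benign_labels = tolower(benign_labels),
                 on_missing_parent = match.arg(on_missing_parent)),
            class = "prioritization_params")
}

gt_dose <- function(gt) {
  # alt-allele dose per genotype string; NA for missing; hemizygous "1" -> 2
  vapply(strsplit(as.character(gt), "[/|]"), function(a) {
    if (any(is.na(a)) || any(a == ".")) return(NA_real_)
    a <- as.integer(a)
    if (length(a) == 1L) return(if (a > 0) 2 else 0)
    if (a[1] == a[2]) (a[1] > 0) * 2 else 1
  }, numeric(1))
}

#' Autosomal-recessive segregation filter
#'
#' Passes iff every affected member is homozygous for the alternate
#' allele, every genotyped unaffected parent of an affected member is
#' heterozygous, and no unaffected member is homozygous-alt.
#'
#' @param gt named character vector of genotypes for one variant, names =
#'   sample ids.
#' @param ped a [pedigree].
#' @param params a [prioritization_params] object (controls the handling
#'   of missing parental genotypes).
#' @return List with `pass` (logical) and `reason` (`NULL`,
#'   `"fails_segregation"` or `"missing_data"`).
#' @export
segregation_filter <- function(gt, ped, params = prioritization_params()) {
  aff <- affected_ids(ped)
  stopifnot(length(aff) > 0)
  parents <- unique(stats::na.omit(c(ped$father[ped$affected],
                                     ped$mother[ped$affected])))
  unaff_parents <- parents[!ped$affected[match(parents, ped$id)]]
  unaffected <- ped$id[!ped$affected]
  dose <- gt_dose(gt)
  names(dose) <- names(gt)

  d_aff <- dose[aff]
  if (anyNA(d_aff)) return(list(pass = FALSE, reason = "missing_data"))
  if (any(d_aff != 2)) return(list(pass = FALSE, reason = "fails_segregation"))

  d_par <- dose[intersect(unaff_parents, names(dose))]
  unseen_parents <- setdiff(unaff_parents, names(dose))
  if ((anyNA(d_par) || length(unseen_parents)) &&
      params$on_missing_parent == "fail") {
    return(list(pass = FALSE, reason = "missing_data"))
  }
  if (any(d_par != 1, na.rm = TRUE)) {
    return(list(pass = FALSE, reason = "fails_segregation"))
  }
  d_un <- dose[intersect(unaffected, names(dose))]
  if (any(d_un == 2, na.rm = TRUE)) {
    return(list(pass = FALSE, reason = "fails_segregation"))
  }
  list(pass = TRUE, reason = NULL)
}

#' Population frequency / control homozygote filter
#'
#' Fails iff the variant's allele frequency exceeds the prevalence cutoff
#' in any database, or any control database holds a homozygote. Control
#' heterozygote counts alone never exclude under a recessive model; they
#' are reported as context only.
#'
#' @param bundle an [annotation_bundle].
#' @param params a [prioritization_params] object.
#' @return List with `pass` and `reasons` (character vector, subset of
#'   `c("frequency_exceeds_cutoff", "control_homozygote")`).
#' @export
frequency_filter <- function(bundle, params = prioritization_params()) {
  reasons <- character()
  if (length(bundle$frequency) &&
      any(bundle$frequency > params$freq_cutoff)) {
    reasons <- c(reasons, "frequency_exceeds_cutoff")
  }
  if (length(bundle$hom_count) && any(bundle$hom_count > 0)) {
    reasons <- c(reasons, "control_homozygote")
  }
  list(pass = !length(reasons), reasons = reasons)
}

#' Shared-ROH containment filter
#'
#' Passes iff the variant position lies inside one of the shared
#' autozygous intervals (1-based inclusive bounds).
#'
#' @param chrom,pos variant coordinate.
#' @param shared shared interval data frame (from [intersect_roh()] or
#'   `autozygome()$shared`).
#' @return Logical.
#' @export
roh_containment_filter <- function(chrom, pos, shared) {
  if (!nrow(shared)) return(FALSE)
  any(shared$chrom == chrom & shared$start <= pos & pos <= shared$end)
}

#' Rank shared homozygous candidates by the recessive exclusion cascade
#'
#' Applies, independently per candidate: segregation, per-database
#' frequency and control-homozygote screening, shared-ROH containment,
#' the clinical phenotype-match flag, and the combined
#' benign-prediction/low-conservation rule (fires iff no prediction label
#' is damaging-class AND the conservation score is known and below the
#' cutoff). A candidate is retained iff no reason fires. The filters are
#' order-independent by construction; output is ordered retained first,
#' then by number of reasons, ties broken by variant id.
#'
#' @param vs a [variant_set] holding (at least) the candidate sites.
#' @param candidates character vector of candidate variant ids (rows of
#'   `vs$sites$id`); duplicates are an error.
#' @param ann named list of [annotation_bundle]s keyed by variant id.
#' @param ped a [pedigree].
#' @param shared shared-ROH interval data frame.
#' @param params a [prioritization_params] object.
#' @return Data frame of class `candidate_verdicts`: columns `variant`,
#'   `status` (`"retained"`/`"excluded"`), `reasons` (comma-joined),
#'   `n_reasons`.
#' @export
exclusion_rank <- function(vs, candidates, ann, ped, shared,
                           params = prioritization_params()) {
  if (anyDuplicated(candidates)) {
    stop("duplicate candidate variant id(s): ",
         paste(unique(candidates[duplicated(candidates)]), collapse = ", "))
  }
  rows <- lapply(candidates, function(vid) {
    i <- match(vid, vs$sites$id)
    if (is.na(i)) stop("candidate '", vid, "' not found in variant set")
    bundle <- ann[[vid]] %||% annotation_bundle()
    reasons <- character()

    seg <- segregation_filter(stats::setNames(vs$gt[i, ], vs$samples), ped,
                              params)
    if (!seg$pass) reasons <- c(reasons, seg$reason)

    freq <- frequency_filter(bundle, params)
    reasons <- c(reasons, freq$reasons)

    if (!roh_containment_filter(vs$sites$chrom[i], vs$sites$pos[i], shared)) {
      reasons <- c(reasons, "outside_shared_roh")
    }
    if (identical(bundle$phenotype_match, "no")) {
      reasons <- c(reasons, "phenotype_mismatch")
    }
    labels <- tolower(bundle$predictions)
    no_damaging <- !any(labels %in% params$damaging_labels)
    cons <- bundle$conservation
    if (no_damaging && !is.null(cons) && !is.na(cons) &&
        cons < params$benign_conservation_cutoff) {
      reasons <- c(reasons, "benign_prediction_low_conservation")
    }
    data.frame(variant = vid,
               status = if (length(reasons)) "excluded" else "retained",
               reasons = paste(reasons, collapse = ","),
               n_reasons = length(reasons),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(variant = character(), status = character(),
                      reasons = character(), n_reasons = integer(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$status != "retained", out$n_reasons, out$variant), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_verdicts", "data.frame")
  out
}

#' @export
print.candidate_verdicts <- function(x, ...) {
  cat(sprintf("Candidate verdicts: %d retained, %d excluded\n",
              sum(x$status == "retained"), sum(x$status == "excluded")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Default pseudoautosomal regions (GRCh37/hg19, X chromosome)
#'
#' @return Data frame with 1-based inclusive `start`/`end` of PAR1/PAR2.
#' @export
par_regions_hg19 <- function() {
  data.frame(name = c("PAR1", "PAR2"),
             start = c(60001L, 154931044L),
             end = c(2699520L, 155260560L))
}

#' Scan the X chromosome for shared hemizygous candidates
#'
#' For all-male affected sibships: returns rare (frequency-filter
#' passing) X-chromosome variants outside the pseudoautosomal regions
#' that are carried hemizygously (called `1` or homozygous-alt) by every
#' affected male and by no unaffected male. Skipped with a notice if any
#' affected member is female.
#'
#' @param vs a [variant_set] containing X-chromosome records.
#' @param ped a [pedigree].
#' @param ann named list of [annotation_bundle]s.
#' @param params a [prioritization_params] object.
#' @param par data frame of pseudoautosomal intervals (default hg19).
#' @param x_chrom chromosome names treated as X.
#' @return Data frame of candidate sites (possibly empty).
#' @export
x_hemizygous_scan <- function(vs, ped, ann = list(),
                              params = prioritization_params(),
                              par = par_regions_hg19(),
                              x_chrom = c("X", "chrX")) {
  empty <- vs$sites[0, , drop = FALSE]
  aff <- affected_ids(ped)
  if (any(ped$sex[match(aff, ped$id)] == "female")) {
    message("x_hemizygous_scan: affected female present; ",
            "hemizygous scan skipped")
    return(empty)
  }
  on_x <- vs$sites$chrom %in% x_chrom
  in_par <- rep(FALSE, nrow(vs$sites))
  for (k in seq_len(nrow(par))) {
    in_par <- in_par | (on_x & vs$sites$pos >= par$start[k] &
                          vs$sites$pos <= par$end[k])
  }
  idx <- which(on_x & !in_par)
  if (!length(idx)) return(empty)
  unaff_males <- ped$id[!ped$affected & ped$sex == "male"]
  unaff_males <- intersect(unaff_males, vs$samples)
  keep <- vapply(idx, function(i) {
    dose <- gt_dose(vs$gt[i, ])
    names(dose) <- vs$samples
    if (anyNA(dose[aff]) || any(dose[aff] != 2)) return(FALSE)
    if (any(dose[unaff_males] == 2, na.rm = TRUE)) return(FALSE)
    vid <- vs$sites$id[i]
    frequency_filter(ann[[vid]] %||% annotation_bundle(), params)$pass
  }, TRUE)
  out <- vs$sites[idx[keep], , drop = FALSE]
  rownames(out) <- NULL
  out
}
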