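#' Configuration for the consanguineous-family simulator
#'
#' Defaults describe a desk-sized study: two 50-Mb autosomes with 5
#' informative SNV markers per Mb, a linear physical-genetic map of
#' 1 cM/Mb with Poisson (no-interference) crossovers, founder marker
#' allele frequencies drawn uniformly from [0.1, 0.5], one planted
#' loss-of-function deletion on a grandparental haplotype, three decoy
#' shared-homozygous variants with database profiles that the filter
#' cascade must exclude, and mild genotype/depth/quality noise.
#'
#' @param n_chromosomes number of autosomes.
#' @param chrom_length_bp autosome length (bp).
#' @param marker_density markers per Mb.
#' @param recombination_rate cM per Mb.
#' @param founder_af_range range of founder marker allele frequencies.
#' @param planted list with `chrom` (index) and `pos` (bp): the causal
#'   1-bp deletion, placed on the first haplotype of the first shared
#'   grandparent.
#' @param n_decoys number of decoy shared-homozygous variants; the first
#'   three carry, in order, a control-homozygote profile, a
#'   phenotype-mismatch profile and a benign-prediction/low-conservation
#'   profile; further decoys carry a common-frequency (2%) profile.
#' @param genotype_error_rate probability a called genotype is flipped to
#'   one of the other two genotypes.
#' @param depth_mean mean read depth per call.
#' @param depth_dispersion negative-binomial size parameter; 0 gives a
#'   constant depth equal to `depth_mean` (exact noise-free limit).
#' @param gq_mean,gq_sd genotype-quality model (normal, clamped to
#'   [0, 99]; `gq_sd = 0` gives constant GQ).
#' @param seq_error_rate per-read probability of the wrong allele.
#' @param x_chromosome also simulate an X chromosome (male hemizygosity).
#' @param x_length_bp X-chromosome length (bp).
#' @param require_segregating resample the gene drop until both affected
#'   children are homozygous for the planted haplotype (the study design
#'   being emulated); with `FALSE` a single unconditional drop is taken
#'   and a non-segregating outcome is flagged in the truth record.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2L, chrom_length_bp = 5e7,
                       marker_density = 5, recombination_rate = 1.0,
                       founder_af_range = c(0.1, 0.5),
                       planted = list(chrom = 1L, pos = 2.5e7),
                       n_decoys = 3L, genotype_error_rate = 0.001,
                       depth_mean = 30, depth_dispersion = 8,
                       gq_mean = 60, gq_sd = 15, seq_error_rate = 0.005,
                       x_chromosome = FALSE, x_length_bp = 2e7,
                       require_segregating = TRUE) {
  stopifnot(n_chromosomes >= 1, chrom_length_bp > 0, marker_density > 0,
            recombination_rate >= 0, genotype_error_rate >= 0,
            depth_mean > 0, depth_dispersion >= 0, gq_sd >= 0,
            seq_error_rate >= 0,
            planted$chrom >= 1, planted$chrom <= n_chromosomes,
            planted$pos >= 1, planted$pos <= chrom_length_bp)
  structure(as.list(environment()), class = "sim_config")
}

#' Noise-free simulator configuration
#'
#' Convenience wrapper over [sim_config()] setting genotype error,
#' sequencing error, depth dispersion and GQ spread all to zero, so that
#' call classification is exact at every truly homozygous site.
#'
#' @param ... overrides passed to [sim_config()].
#' @export
sim_config_noise_free <- function(...) {
  sim_config(genotype_error_rate = 0, depth_dispersion = 0, gq_sd = 0,
             seq_error_rate = 0, ...)
}

#' The ten-member first-cousin pedigree
#'
#' One shared grandparental couple, their two children married to two
#' unrelated spouses, producing two first cousins who marry and have two
#' affected boys. The parents' kinship coefficient is 1/16, hence each
#' child's expected inbreeding coefficient is 1/16.
#'
#' @return A [pedigree] object.
#' @export
first_cousin_pedigree <- function() {
  pedigree(
    id       = c("gp1", "gp2", "u1", "u1.sp", "u2", "u2.sp",
                 "father", "mother", "II.1", "II.2"),
    sex      = c("male", "female", "male", "female", "female", "male",
                 "male", "female", "male", "male"),
    affected = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                 FALSE, FALSE, TRUE, TRUE),
    father   = c(NA, NA, "gp1", NA, "gp1", NA, "u1", "u2.sp", "father",
                 "father"),
    mother   = c(NA, NA, "gp2", NA, "gp2", NA, "u1.sp", "u2", "mother",
                 "mother")
  )
}

# --- haplotype segment algebra ------------------------------------------
# a haplotype on (0, L] is a vector of segment end positions `bp`
# (last element = L) and parallel founder-haplotype labels `lab`

founder_hap <- function(L, label) list(bp = L, lab = label)

hap_label_at <- function(h, x) {
  h$lab[findInterval(x, c(0, h$bp), left.open = TRUE)]
}

hap_slice <- function(h, a, b) {
  starts <- c(0, h$bp[-length(h$bp)])
  keep <- h$bp > a & starts < b
  list(bp = pmin(h$bp[keep], b), lab = h$lab[keep])
}

hap_merge <- function(h) {
  if (length(h$lab) <= 1L) return(h)
  same <- c(h$lab[-1L] == h$lab[-length(h$lab)], FALSE)
  list(bp = h$bp[!same], lab = h$lab[!same])
}

# one meiosis: Poisson crossovers at rate cM/Mb on a linear map
meiosis <- function(h1, h2, L, cM_per_Mb) {
  n_x <- stats::rpois(1L, L / 1e6 * cM_per_Mb / 100)
  cuts <- sort(stats::runif(n_x, 0, L))
  bounds <- c(0, cuts, L)
  phase <- sample.int(2L, 1L)
  pieces <- lapply(seq_len(length(bounds) - 1L), function(k) {
    h <- if ((phase + k) %% 2L == 0L) h1 else h2
    hap_slice(h, bounds[k], bounds[k + 1L])
  })
  hap_merge(list(bp = unlist(lapply(pieces, `[[`, "bp")),
                 lab = unlist(lapply(pieces, `[[`, "lab"))))
}

# maximal intervals where the two haplotypes carry the same founder label
autozygous_segments <- function(h1, h2, L) {
  cuts <- sort(unique(c(h1$bp, h2$bp)))
  starts <- c(0, cuts[-length(cuts)])
  mids <- (starts + cuts) / 2
  auto <- hap_label_at(h1, mids) == hap_label_at(h2, mids)
  if (!any(auto)) {
    return(data.frame(start = numeric(), end = numeric()))
  }
  r <- rle(auto)
  seg_end <- cumsum(r$lengths)
  seg_start <- seg_end - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[seg_start[keep]], end = cuts[seg_end[keep]])
}

#' Gene-drop haplotypes through a pedigree
#'
#' Founders receive distinct labeled haplotypes; each meiosis draws a
#' Poisson number of crossovers (`length_Mb * rate / 100` expected) with
#' uniform positions and alternates parental haplotypes. The returned
#' truth record carries every member's founder-origin segment mosaic and
#' each affected child's realized autozygous segments.
#'
#' @param ped a [pedigree].
#' @param config a [sim_config].
#' @return List with `haplotypes` (member -> chromosome -> `h1`/`h2`),
#'   `autozygous` (affected member -> chromosome -> segment data frame),
#'   `chrom_lengths`.
#' @export
gene_drop <- function(ped, config = sim_config()) {
  chroms <- as.character(seq_len(config$n_chromosomes))
  lens <- stats::setNames(rep(config$chrom_length_bp, length(chroms)), chroms)
  if (config$x_chromosome) {
    lens <- c(lens, X = config$x_length_bp)
    chroms <- names(lens)
  }
  ord <- order(pedigree_depth(ped))
  haps <- list()
  for (i in ord) {
    id <- ped$id[i]
    fa <- ped$father[i]; mo <- ped$mother[i]
    male <- ped$sex[i] == "male"
    haps[[id]] <- lapply(stats::setNames(chroms, chroms), function(ch) {
      L <- lens[[ch]]
      if (is.na(fa)) { # founder
        if (ch == "X" && male) {
          list(h1 = founder_hap(L, paste0(id, "_X")), h2 = NULL)
        } else {
          list(h1 = founder_hap(L, paste0(id, "_1")),
               h2 = founder_hap(L, paste0(id, "_2")))
        }
      } else if (ch == "X") {
        mo_h <- haps[[mo]][[ch]]
        mat <- meiosis(mo_h$h1, mo_h$h2, L, config$recombination_rate)
        if (male) list(h1 = mat, h2 = NULL)
        else list(h1 = haps[[fa]][[ch]]$h1, h2 = mat)
      } else {
        fa_h <- haps[[fa]][[ch]]; mo_h <- haps[[mo]][[ch]]
        list(h1 = meiosis(fa_h$h1, fa_h$h2, L, config$recombination_rate),
             h2 = meiosis(mo_h$h1, mo_h$h2, L, config$recombination_rate))
      }
    })
  }
  aff <- affected_ids(ped)
  autoz <- lapply(stats::setNames(aff, aff), function(id) {
    lapply(stats::setNames(chroms, chroms), function(ch) {
      h <- haps[[id]][[ch]]
      if (is.null(h$h2)) {
        data.frame(start = numeric(), end = numeric()) # hemizygous X
      } else {
        autozygous_segments(h$h1, h$h2, lens[[ch]])
      }
    })
  })
  list(haplotypes = haps, autozygous = autoz, chrom_lengths = lens)
}

#' Realized autozygous genome fraction of one member
#'
#' @param drop result of [gene_drop()].
#' @param id affected member id.
#' @param autosomes_only exclude the X chromosome from both numerator and
#'   denominator (default).
#' @return Fraction of the genome lying in autozygous segments.
#' @export
autozygous_fraction <- function(drop, id, autosomes_only = TRUE) {
  chroms <- names(drop$chrom_lengths)
  if (autosomes_only) chroms <- setdiff(chroms, "X")
  tot <- sum(vapply(chroms, function(ch) {
    s <- drop$autozygous[[id]][[ch]]
    sum(s$end - s$start)
  }, 0))
  tot / sum(drop$chrom_lengths[chroms])
}

hap_dose_at <- function(hap_pair, pos, carrier) {
  d <- as.integer(identical(hap_label_at(hap_pair$h1, pos), carrier))
  if (!is.null(hap_pair$h2)) {
    d <- d + as.integer(identical(hap_label_at(hap_pair$h2, pos), carrier))
  }
  d
}

decoy_profiles <- function() {
  list(
    control_hom = annotation_bundle(
      frequency = c(ESP6500 = 16 / 13006),
      het_count = c(ESP6500 = 16), hom_count = c(inhouse = 1),
      phenotype_match = "unknown"),
    phenotype = annotation_bundle(
      phenotype_match = "no", disease_link = "macular degeneration"),
    benign = annotation_bundle(
      frequency = c(ESP6500 = 7 / 13006), het_count = c(ESP6500 = 7),
      predictions = c(SIFT = "tolerated", PolyPhen2 = "possibly damaging"),
      conservation = 1.101, phenotype_match = "unknown"),
    common = annotation_bundle(
      frequency = c(`1000Genomes` = 0.02), phenotype_match = "unknown")
  )
}

planted_profile <- function() {
  annotation_bundle(
    frequency = c(`1000Genomes` = 0, ESP6500 = 0, dbSNP138 = 0,
                  inhouse = 0),
    conservation = 4.9, phenotype_match = "yes"
  )
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

noisy_calls <- function(true_gt, config) {
  n <- length(true_gt)
  dose <- c("0/0" = 0, "0/1" = 1, "1/1" = 2)[true_gt]
  flip <- stats::runif(n) < config$genotype_error_rate
  if (any(flip)) {
    dose[flip] <- vapply(dose[flip],
                         function(d) sample(setdiff(0:2, d), 1L), 0)
  }
  called <- c("0/0", "0/1", "1/1")[dose + 1L]
  depth <- if (config$depth_dispersion == 0) {
    rep(round(config$depth_mean), n)
  } else {
    stats::rnbinom(n, size = config$depth_dispersion, mu = config$depth_mean)
  }
  depth <- pmax(depth, 1L)
  p_alt <- c(config$seq_error_rate, 0.5, 1 - config$seq_error_rate)[dose + 1L]
  alt <- stats::rbinom(n, depth, p_alt)
  gq <- if (config$gq_sd == 0) rep(config$gq_mean, n) else {
    round(stats::rnorm(n, config$gq_mean, config$gq_sd))
  }
  list(gt = called, gq = clamp(gq, 0, 99),
       ad = paste(depth - alt, alt, sep = ","))
}

#' Simulate a sequenced first-cousin family
#'
#' Runs the full generator: gene drop through [first_cousin_pedigree()],
#' marker genotyping of the sequenced quartet (both parents and the two
#' affected boys), planting of the causal deletion plus decoy
#' shared-homozygous variants with their annotation profiles, and the
#' depth/quality/genotype-error noise model. The planted variant's
#' genotypes follow descent; a replicate in which the two children are
#' not both homozygous is flagged `segregating = FALSE` in the truth
#' record (not resampled).
#'
#' @param config a [sim_config].
#' @param seed integer seed; fixing it makes the whole object (and the
#'   files written by [sim_write()]) reproducible.
#' @return Object of class `consang_sim`: list with `config`, `pedigree`,
#'   `drop` (gene-drop truth), `truth` (planted/decoy record), `markers`,
#'   `vs` (a [variant_set] of the quartet's calls) and `annotations`.
#' @export
simulate_family <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ped <- first_cousin_pedigree()
  quartet <- c("father", "mother", "II.1", "II.2")
  carrier <- "gp1_1"
  p_chrom <- as.character(config$planted$chrom)
  p_pos <- config$planted$pos
  seg_ok <- function(drop) {
    all(vapply(c("II.1", "II.2"), function(s)
      hap_dose_at(drop$haplotypes[[s]][[p_chrom]], p_pos, carrier),
      0L) == 2L)
  }
  attempts <- 1L
  drop <- gene_drop(ped, config)
  if (config$require_segregating) {
    while (!seg_ok(drop) && attempts < 20000L) {
      attempts <- attempts + 1L
      drop <- gene_drop(ped, config)
    }
  }
  chroms <- names(drop$chrom_lengths)

  # markers: positions, allele frequencies, founder haplotype alleles
  founders <- ped$id[is.na(ped$father)]
  hap_labels <- unlist(lapply(founders, function(f) paste0(f, c("_1", "_2"))))
  markers <- do.call(rbind, lapply(chroms, function(ch) {
    L <- drop$chrom_lengths[[ch]]
    n <- max(1L, round(L / 1e6 * config$marker_density))
    pos <- sort(sample.int(L - 1L, n))
    af <- stats::runif(n, config$founder_af_range[1],
                       config$founder_af_range[2])
    data.frame(chrom = ch, pos = pos, af = af, stringsAsFactors = FALSE)
  }))
  ref_alt <- t(vapply(seq_len(nrow(markers)), function(i) {
    sample(c("A", "C", "G", "T"), 2L)
  }, character(2)))
  markers$ref <- ref_alt[, 1]; markers$alt <- ref_alt[, 2]
  x_labels <- if (config$x_chromosome) {
    c(paste0(setdiff(founders, ped$id[ped$sex == "male"]), "_1"),
      paste0(setdiff(founders, ped$id[ped$sex == "male"]), "_2"),
      paste0(intersect(founders, ped$id[ped$sex == "male"]), "_X"))
  } else character()
  all_labels <- union(hap_labels, x_labels)
  founder_alleles <- matrix(
    stats::rbinom(length(all_labels) * nrow(markers), 1L,
                  rep(markers$af, each = length(all_labels))),
    nrow = length(all_labels), dimnames = list(all_labels, NULL))

  # true marker genotypes of the quartet, by founder-label lookup
  true_gt <- matrix("0/0", nrow(markers), length(quartet),
                    dimnames = list(NULL, quartet))
  for (s in quartet) {
    for (ch in chroms) {
      i <- which(markers$chrom == ch)
      hp <- drop$haplotypes[[s]][[ch]]
      l1 <- hap_label_at(hp$h1, markers$pos[i])
      a1 <- founder_alleles[cbind(match(l1, all_labels), i)]
      if (is.null(hp$h2)) { # hemizygous male X
        true_gt[i, s] <- ifelse(a1 > 0, "1/1", "0/0")
      } else {
        l2 <- hap_label_at(hp$h2, markers$pos[i])
        a2 <- founder_alleles[cbind(match(l2, all_labels), i)]
        true_gt[i, s] <- c("0/0", "0/1", "1/1")[a1 + a2 + 1L]
      }
    }
  }

  # planted causal deletion: rides the first haplotype of grandparent gp1
  planted_dose <- vapply(ped$id, function(s)
    hap_dose_at(drop$haplotypes[[s]][[p_chrom]], p_pos, carrier), 0L)
  segregating <- all(planted_dose[c("II.1", "II.2")] == 2L)

  # decoys: shared homozygous by construction, excluded by annotation
  profiles <- decoy_profiles()
  n_dec <- config$n_decoys
  decoys <- NULL
  if (n_dec > 0) {
    prof_idx <- c(seq_len(min(n_dec, 3L)),
                  rep(4L, max(0L, n_dec - 3L)))
    d_chrom <- sample(setdiff(chroms, "X"), n_dec, replace = TRUE)
    d_pos <- vapply(d_chrom, function(ch)
      sample.int(drop$chrom_lengths[[ch]] - 1L, 1L), 0L)
    decoys <- data.frame(
      id = paste0("decoy", seq_len(n_dec)),
      chrom = d_chrom, pos = d_pos,
      profile = names(profiles)[prof_idx],
      stringsAsFactors = FALSE)
  }

  # assemble the site table: markers + planted + decoys, sorted
  marker_sites <- data.frame(
    chrom = markers$chrom, pos = markers$pos,
    id = paste0("m", markers$chrom, "_", seq_len(nrow(markers))),
    ref = markers$ref, alt = markers$alt, stringsAsFactors = FALSE)
  planted_site <- data.frame(chrom = p_chrom, pos = p_pos, id = "planted",
                             ref = "AC", alt = "A")
  extra_sites <- rbind(planted_site, if (!is.null(decoys)) {
    data.frame(chrom = decoys$chrom, pos = decoys$pos, id = decoys$id,
               ref = "G", alt = "A")
  })
  sites <- rbind(marker_sites, extra_sites)

  extra_gt <- matrix("0/0", nrow(extra_sites), length(quartet),
                     dimnames = list(NULL, quartet))
  extra_gt[1, ] <- c("0/0", "0/1", "1/1")[planted_dose[quartet] + 1L]
  if (!is.null(decoys)) {
    for (k in seq_len(nrow(decoys))) {
      extra_gt[k + 1L, ] <- c("0/1", "0/1", "1/1", "1/1")
    }
  }
  gt_true_all <- rbind(true_gt, extra_gt)
  o <- order(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]
  gt_true_all <- gt_true_all[o, , drop = FALSE]

  # noise model, drawn per sample in fixed order
  gt <- ad <- matrix(NA_character_, nrow(sites), length(quartet),
                     dimnames = list(NULL, quartet))
  gq_num <- matrix(NA_real_, nrow(sites), length(quartet),
                   dimnames = list(NULL, quartet))
  for (s in quartet) {
    nc <- noisy_calls(gt_true_all[, s], config)
    gt[, s] <- nc$gt; gq_num[, s] <- nc$gq; ad[, s] <- nc$ad
  }
  vs <- variant_set(sites, gt, gq_num, ad)

  ann <- c(list(planted = planted_profile()),
           if (!is.null(decoys)) {
             stats::setNames(profiles[decoys$profile], decoys$id)
           })

  structure(list(
    config = config, pedigree = ped, drop = drop,
    truth = list(planted = list(chrom = p_chrom, pos = p_pos,
                                carrier = carrier, dose = planted_dose),
                 segregating = segregating, drop_attempts = attempts,
                 decoys = decoys, true_gt = gt_true_all, sites = sites),
    markers = markers, vs = vs, annotations = ann,
    samples = quartet
  ), class = "consang_sim")
}

#' @export
print.consang_sim <- function(x, ...) {
  cat(sprintf(paste0(
    "Simulated first-cousin family: %d chromosome(s) x %.0f Mb, ",
    "%d sites, %d samples\n"),
    x$config$n_chromosomes + x$config$x_chromosome,
    x$config$chrom_length_bp / 1e6, nrow(x$vs$sites), length(x$samples)))
  cat(sprintf("  planted variant %s:%d (segregating: %s), %d decoy(s)\n",
              x$truth$planted$chrom, x$truth$planted$pos,
              x$truth$segregating,
              if (is.null(x$truth$decoys)) 0L else nrow(x$truth$decoys)))
  for (id in names(x$drop$autozygous)) {
    cat(sprintf("  %s autozygous fraction: %.4f\n", id,
                autozygous_fraction(x$drop, id)))
  }
  invisible(x)
}

#' Write simulator output to disk
#'
#' Emits `sim.vcf` (plain-text VCF of the quartet), `sim.ped` (full
#' ten-member pedigree), `sim.annotations.tsv` and `truth.json`. With a
#' fixed seed in [simulate_family()] the files are byte-identical across
#' runs.
#'
#' @param sim a `consang_sim` object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
sim_write <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_variants(sim$vs, file.path(dir, "sim.vcf"))
  write_pedigree(sim$pedigree, file.path(dir, "sim.ped"))
  write_annotations(sim$annotations, file.path(dir, "sim.annotations.tsv"))
  autoz <- lapply(sim$drop$autozygous, function(per_chrom) {
    lapply(per_chrom, function(df) as.list(df))
  })
  truth <- list(
    planted = sim$truth$planted[c("chrom", "pos", "carrier")],
    planted_dose = as.list(sim$truth$planted$dose),
    segregating = sim$truth$segregating,
    decoys = sim$truth$decoys,
    autozygous_segments = autoz,
    autozygous_fraction = lapply(
      stats::setNames(names(autoz), names(autoz)),
      function(id) autozygous_fraction(sim$drop, id))
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Run the full mapping-and-prioritization pipeline on a simulated family
#'
#' Maps the autozygome of the two affected children, takes the annotated
#' variants (planted + decoys) as the shared-homozygosity candidate set
#' and applies the exclusion cascade.
#'
#' @param sim a `consang_sim` object.
#' @param roh a [roh_params] object.
#' @param pri a [prioritization_params] object.
#' @return List with `autozygome`, `verdicts` and `retained` (ids).
#' @export
recover_candidate <- function(sim, roh = roh_params(),
                              pri = prioritization_params()) {
  az <- autozygome(sim$vs, sim$pedigree, roh)
  candidates <- names(sim$annotations)
  verdicts <- exclusion_rank(sim$vs, candidates, sim$annotations,
                             sim$pedigree, az$shared, pri)
  list(autozygome = az, verdicts = verdicts,
       retained = verdicts$variant[verdicts$status == "retained"])
}
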