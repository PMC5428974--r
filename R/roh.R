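#' Parameters for run-of-homozygosity detection
#'
#' Defaults implement the rule: a run of at least four consecutive
#' high-quality homozygous SNVs (genotype quality >= 20, total read depth
#' >= 10, called-allele fraction >= 0.9) uninterrupted by heterozygous
#' SNVs; shared runs across affected individuals are reported only when
#' longer than 1 Mb.
#'
#' @param min_gq minimum genotype quality for a high-quality homozygote.
#' @param min_depth minimum total read depth (sum of allelic depths).
#' @param min_allele_fraction minimum called-allele depth over total
#'   depth; must lie in (0.5, 1].
#' @param min_run minimum number of supporting high-quality homozygous
#'   SNVs per run.
#' @param min_shared_length minimum length (bp) of a *shared* interval;
#'   per-sample intervals are not length-filtered.
#' @param het_min_gq minimum GQ for a heterozygous call to interrupt a
#'   run; 0 (default) means any called het interrupts.
#' @param max_gap maximum physical distance (bp) between consecutive
#'   supporting SNVs; `Inf` (default) imposes no gap limit.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(min_gq = 20, min_depth = 10, min_allele_fraction = 0.9,
                       min_run = 4L, min_shared_length = 1e6,
                       het_min_gq = 0, max_gap = Inf) {
  stopifnot(min_gq > 0, min_depth > 0, min_run > 0, min_shared_length > 0,
            max_gap > 0, het_min_gq >= 0)
  if (min_allele_fraction <= 0.5 || min_allele_fraction > 1) {
    stop("min_allele_fraction must lie in (0.5, 1]")
  }
  structure(list(min_gq = min_gq, min_depth = min_depth,
                 min_allele_fraction = min_allele_fraction,
                 min_run = as.integer(min_run),
                 min_shared_length = min_shared_length,
                 het_min_gq = het_min_gq, max_gap = max_gap),
            class = "roh_params")
}

#' Classify one genotype call for ROH support
#'
#' @param gt VCF-style genotype string (e.g. `"1/1"`, `"0/1"`, `"./."`).
#' @param gq genotype quality (phred-like), `NA` allowed.
#' @param ad comma-joined allelic depths, reference allele first.
#' @param params a [roh_params] object.
#' @return One of `"HQ_HOM"`, `"HET"`, `"LOW_QUALITY"`, `"MISSING"`.
#'   `HQ_HOM` requires a homozygous genotype with GQ, total depth and
#'   called-allele fraction all meeting the thresholds; any called het is
#'   `HET` (subject to `het_min_gq`); uncalled genotypes are `MISSING`;
#'   everything else is `LOW_QUALITY`.
#' @examples
#' p <- roh_params()
#' classify_call("1/1", 30, "0,15", p)  # HQ_HOM
#' classify_call("1/1", 25, "2,9", p)   # LOW_QUALITY: fraction 9/11 < 0.9
#' @export
classify_call <- function(gt, gq, ad, params = roh_params()) {
  unname(classify_calls(matrix(gt, 1, 1, dimnames = list(NULL, "s")),
                        matrix(gq, 1, 1), matrix(ad, 1, 1), params)[1, 1])
}

#' Classify all calls of a variant set (vectorized)
#'
#' @param gt,gq,ad matrices as stored in a [variant_set], or a
#'   `variant_set` may be given as `gt` with `gq`/`ad` omitted.
#' @param params a [roh_params] object.
#' @return Character matrix of call classes, same shape as `gt`.
#' @export
classify_calls <- function(gt, gq = NULL, ad = NULL, params = roh_params()) {
  if (inherits(gt, "variant_set")) {
    vs <- gt; gt <- vs$gt; gq <- vs$gq; ad <- vs$ad
  }
  dm <- dim(gt)
  dn <- dimnames(gt)
  gt <- as.character(gt); gq <- as.numeric(gq); ad <- as.character(ad)
  alleles <- strsplit(gt, "[/|]")
  a1 <- vapply(alleles, function(a) a[1] %||% ".", "")
  a2 <- vapply(alleles, function(a) if (length(a) >= 2L) a[2] else a[1], "")
  missing <- is.na(gt) | a1 == "." | a2 == "."
  het <- !missing & a1 != a2
  hom <- !missing & a1 == a2

  cls <- rep("LOW_QUALITY", length(gt))
  cls[missing] <- "MISSING"
  gq0 <- ifelse(is.na(gq), -Inf, gq)
  cls[het] <- ifelse(gq0[het] >= params$het_min_gq, "HET", "LOW_QUALITY")

  if (any(hom)) {
    depths <- suppressWarnings(
      lapply(strsplit(ifelse(is.na(ad), "", ad)[hom], ",", fixed = TRUE),
             as.numeric))
    if (any(unlist(depths) < 0, na.rm = TRUE)) {
      stop("negative allelic depth")
    }
    idx <- as.integer(a1[hom]) + 1L
    total <- vapply(depths, function(d) sum(d, na.rm = TRUE), 0)
    called <- mapply(function(d, i) {
      if (length(d) >= i && !is.na(d[i])) d[i] else NA_real_
    }, depths, idx)
    frac <- ifelse(total > 0, called / total, NA_real_)
    ok <- gq0[hom] >= params$min_gq & total >= params$min_depth &
      !is.na(frac) & frac >= params$min_allele_fraction
    cls[hom] <- ifelse(ok, "HQ_HOM", "LOW_QUALITY")
  }
  if (!is.null(dm)) {
    dim(cls) <- dm
    dimnames(cls) <- dn
  }
  cls
}

#' Detect runs of homozygosity on one chromosome for one sample
#'
#' A run is a maximal stretch of consecutive `HQ_HOM` SNVs containing no
#' `HET` site and at least `min_run` supporting SNVs. `LOW_QUALITY` and
#' `MISSING` sites are transparent: they neither extend nor break runs.
#' The reported interval spans the first to the last supporting SNV.
#'
#' @param pos sorted 1-based positions of the classified SNV sites.
#' @param class call classes from [classify_calls()] for these sites.
#' @param params a [roh_params] object.
#' @param chrom chromosome name recorded in the output.
#' @param sample sample id recorded in the output.
#' @return Data frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive), `n_snvs`, `sample`.
#' @export
detect_roh <- function(pos, class, params = roh_params(), chrom = "chr",
                       sample = "sample") {
  stopifnot(length(pos) == length(class))
  if (is.unsorted(pos, strictly = FALSE)) {
    stop("site positions must be sorted in ascending order")
  }
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_snvs = integer(),
                      sample = character(), stringsAsFactors = FALSE)
  keep <- class %in% c("HQ_HOM", "HET")
  pos <- pos[keep]; class <- class[keep]
  if (!length(pos)) return(empty)
  # blocks of consecutive informative sites delimited by HETs
  block <- cumsum(class == "HET")
  hom <- class == "HQ_HOM"
  if (is.finite(params$max_gap)) {
    # a long gap between consecutive informative sites splits the block
    gap_break <- c(FALSE, diff(pos) > params$max_gap)
    block <- block + cumsum(gap_break)
  }
  runs <- lapply(split(seq_along(pos)[hom], block[hom]), function(ix) {
    if (length(ix) < params$min_run) return(NULL)
    data.frame(chrom = chrom, start = pos[ix[1]], end = pos[ix[length(ix)]],
               n_snvs = length(ix), sample = sample,
               stringsAsFactors = FALSE)
  })
  runs <- runs[!vapply(runs, is.null, TRUE)]
  if (!length(runs)) return(empty)
  out <- do.call(rbind, runs)
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}

roh_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end)
  )
}

granges_to_roh <- function(gr, sample = "shared") {
  n <- length(gr)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    n_snvs = rep(NA_integer_, n),
    sample = rep(sample, n),
    stringsAsFactors = FALSE
  )
}

#' Intersect per-sample ROH tracks across affected individuals
#'
#' Genomic set-intersection of the samples' interval sets; only pieces at
#' least `min_shared_length` long are kept. With a single sample the
#' result is that sample's track, length-filtered.
#'
#' @param tracks list of per-sample interval data frames (as returned by
#'   [detect_roh()]).
#' @param params a [roh_params] object (supplies `min_shared_length`).
#' @return Data frame of shared intervals (`sample = "shared"`), sorted.
#' @export
intersect_roh <- function(tracks, params = roh_params()) {
  if (!length(tracks)) stop("at least one sample track is required")
  grs <- lapply(tracks, roh_to_granges)
  # disjoint chromosome sets legitimately intersect to nothing; GRanges
  # warns about unshared seqlevels in that case
  shared <- suppressWarnings(
    Reduce(function(a, b) GenomicRanges::intersect(a, b,
                                                   ignore.strand = TRUE),
           grs))
  shared <- shared[GenomicRanges::width(shared) >= params$min_shared_length]
  shared <- GenomicRanges::sort(shared)
  granges_to_roh(shared)
}

#' Map the autozygome of a family from variant calls
#'
#' Composes call classification, per-sample per-chromosome ROH detection
#' and cross-sample intersection for the affected members of a pedigree.
#' Only SNV sites (all alleles single bases) support or interrupt runs;
#' indels are ignored here and retained for prioritization.
#'
#' @param vs a [variant_set].
#' @param ped a [pedigree]; all affected members must be samples of `vs`.
#' @param params a [roh_params] object.
#' @return An object of class `autozygome`: list with `per_sample` (named
#'   list of interval data frames), `shared` (intersection track with
#'   supporting-SNV counts), `params`, `affected`.
#' @export
autozygome <- function(vs, ped, params = roh_params()) {
  stopifnot(inherits(vs, "variant_set"))
  aff <- affected_ids(ped)
  if (!length(aff)) stop("pedigree has no affected member")
  absent <- setdiff(aff, vs$samples)
  if (length(absent)) {
    stop("affected sample(s) absent from the variant set: ",
         paste(absent, collapse = ", "))
  }
  snv <- is_snv(vs$sites)
  sites <- vs$sites[snv, , drop = FALSE]
  cls <- classify_calls(vs$gt[snv, aff, drop = FALSE],
                        vs$gq[snv, aff, drop = FALSE],
                        vs$ad[snv, aff, drop = FALSE], params)
  chroms <- unique(sites$chrom)
  empty_track <- data.frame(chrom = character(), start = integer(),
                            end = integer(), n_snvs = integer(),
                            sample = character(), stringsAsFactors = FALSE)
  per_sample <- lapply(aff, function(s) {
    out <- lapply(chroms, function(ch) {
      i <- sites$chrom == ch
      detect_roh(sites$pos[i], cls[i, s], params, chrom = ch, sample = s)
    })
    rbind(empty_track, do.call(rbind, out))
  })
  names(per_sample) <- aff
  shared <- intersect_roh(per_sample, params)
  if (nrow(shared)) {
    # supporting count for a shared piece: sites HQ_HOM in every affected
    all_hom <- rowSums(cls == "HQ_HOM") == length(aff)
    gr_sites <- GenomicRanges::GRanges(sites$chrom,
                                       IRanges::IRanges(sites$pos, sites$pos))
    hits <- GenomicRanges::countOverlaps(roh_to_granges(shared),
                                         gr_sites[all_hom])
    shared$n_snvs <- as.integer(hits)
  }
  structure(list(per_sample = per_sample, shared = shared,
                 params = params, affected = aff),
            class = "autozygome")
}

is_snv <- function(sites) {
  nchar(sites$ref) == 1L &
    vapply(strsplit(sites$alt, ",", fixed = TRUE),
           function(a) all(nchar(a) == 1L), TRUE)
}

#' @export
print.autozygome <- function(x, ...) {
  cat("Autozygome of", length(x$affected), "affected sample(s):",
      paste(x$affected, collapse = ", "), "\n")
  for (s in names(x$per_sample)) {
    t <- x$per_sample[[s]]
    cat(sprintf("  %s: %d run(s), %.2f Mb\n", s, nrow(t),
                sum(t$end - t$start + 1) / 1e6))
  }
  cat(sprintf("  shared (>= %.2f Mb): %d interval(s), %.2f Mb\n",
              x$params$min_shared_length / 1e6, nrow(x$shared),
              sum(x$shared$end - x$shared$start + 1) / 1e6))
  invisible(x)
}

#' @export
summary.autozygome <- function(object, ...) {
  tracks <- c(object$per_sample, list(shared = object$shared))
  out <- do.call(rbind, lapply(names(tracks), function(nm) {
    t <- tracks[[nm]]
    data.frame(track = nm, n_intervals = nrow(t),
               total_mb = sum(t$end - t$start + 1) / 1e6,
               longest_mb = if (nrow(t)) max(t$end - t$start + 1) / 1e6 else 0)
  }))
  rownames(out) <- NULL
  out
}

#' Plot ROH tracks of an autozygome
#'
#' One horizontal lane per track (affected samples plus the shared
#' intersection), segments drawn at their genomic coordinates, one panel
#' column per chromosome laid end to end.
#'
#' @param x an [autozygome] object.
#' @param ... passed to [graphics::segments()].
#' @export
plot.autozygome <- function(x, ...) {
  tracks <- c(x$per_sample, list(shared = x$shared))
  all_iv <- do.call(rbind, lapply(names(tracks), function(nm) {
    t <- tracks[[nm]]
    if (nrow(t)) cbind(t, track = nm) else NULL
  }))
  chroms <- unique(unlist(lapply(tracks, function(t) t$chrom)))
  if (is.null(all_iv) || !length(chroms)) {
    graphics::plot.new()
    graphics::title("autozygome (no intervals)")
    return(invisible(x))
  }
  chrom_max <- vapply(chroms, function(ch)
    max(all_iv$end[all_iv$chrom == ch]), 0)
  offset <- stats::setNames(c(0, cumsum(chrom_max))[seq_along(chroms)], chroms)
  lanes <- stats::setNames(seq_along(tracks), names(tracks))
  graphics::plot(NA, xlim = c(0, sum(chrom_max)),
                 ylim = c(0.5, length(tracks) + 0.5),
                 yaxt = "n", xlab = "concatenated genomic position (bp)",
                 ylab = "", main = "Runs of homozygosity")
  graphics::axis(2, at = lanes, labels = names(lanes), las = 1)
  graphics::abline(v = cumsum(chrom_max), col = "grey80", lty = 2)
  graphics::segments(offset[all_iv$chrom] + all_iv$start,
                     lanes[all_iv$track],
                     offset[all_iv$chrom] + all_iv$end,
                     lanes[all_iv$track], lwd = 6, ...)
  invisible(x)
}
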