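#' Construct a variant set
#'
#' The in-memory container for multi-sample variant calls: a sites table
#' plus parallel per-sample matrices of genotype (GT), genotype quality
#' (GQ) and allelic depths (AD, comma-joined as in VCF). Coordinates are
#' 1-based throughout; conversion to 0-based half-open happens only at the
#' BED boundary.
#'
#' @param sites data frame with columns `chrom`, `pos` (1-based), `id`,
#'   `ref`, `alt` (comma-joined alternate alleles).
#' @param gt character matrix (sites x samples) of VCF-style genotypes
#'   such as `"0/1"`; `"./."` or `NA` = missing.
#' @param gq numeric matrix of genotype qualities (phred-like), `NA`
#'   allowed.
#' @param ad character matrix of comma-joined allelic depths (ref first).
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(sites, gt, gq, ad) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need %in% names(sites))) {
    stop("sites must have columns ", paste(need, collapse = ", "))
  }
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  if (any(sites$pos < 1L)) stop("positions must be >= 1")
  ok_allele <- function(x) grepl("^[ACGT]+$", x)
  if (nrow(sites) &&
      (!all(ok_allele(sites$ref)) ||
       !all(vapply(strsplit(sites$alt, ","), function(a) all(ok_allele(a)),
                   logical(1))))) {
    stop("alleles must be non-empty uppercase ACGT strings")
  }
  gt <- as.matrix(gt); gq <- as.matrix(gq); ad <- as.matrix(ad)
  dims_ok <- all(nrow(gt) == nrow(sites), nrow(gq) == nrow(sites),
                 nrow(ad) == nrow(sites), ncol(gq) == ncol(gt),
                 ncol(ad) == ncol(gt))
  if (!dims_ok) stop("gt/gq/ad dimensions do not match the sites table")
  if (is.null(colnames(gt))) stop("gt matrix must carry sample names")
  colnames(gq) <- colnames(ad) <- colnames(gt)
  structure(
    list(sites = sites, gt = gt, gq = gq, ad = ad,
         samples = colnames(gt)),
    class = "variant_set"
  )
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d sites x %d samples (%s)\n",
              nrow(x$sites), length(x$samples),
              paste(x$samples, collapse = ", ")))
  invisible(x)
}

#' @export
dim.variant_set <- function(x) c(nrow(x$sites), length(x$samples))

check_site_order <- function(chrom, pos) {
  if (!length(chrom)) return(TRUE)
  r <- rle(chrom)
  if (anyDuplicated(r$values)) return(FALSE) # chromosome blocks interleaved
  all(unlist(tapply(pos, factor(chrom, levels = unique(chrom)),
                    function(p) !is.unsorted(p), simplify = FALSE)))
}

sort_sites <- function(vs) {
  o <- order(vs$sites$chrom, vs$sites$pos)
  variant_set(vs$sites[o, , drop = FALSE], vs$gt[o, , drop = FALSE],
              vs$gq[o, , drop = FALSE], vs$ad[o, , drop = FALSE])
}

#' Read multi-sample variant calls from a VCF file
#'
#' Requires the GT, GQ and AD FORMAT fields on every record. Records must
#' be sorted by (chromosome, position); unsorted input is an error unless
#' `allow_unsorted = TRUE`, in which case records are re-sorted
#' (lexicographic chromosome order).
#'
#' @param path path to a VCF 4.x file.
#' @param allow_unsorted re-sort instead of erroring on unsorted input.
#' @return A [variant_set].
#' @export
read_variants <- function(path, allow_unsorted = FALSE) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e)))
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L) {
    samples <- if (ncol(v@gt) > 1L) colnames(v@gt)[-1L] else character()
    m <- matrix(character(), 0, length(samples),
                dimnames = list(NULL, samples))
    return(variant_set(
      data.frame(chrom = character(), pos = integer(), id = character(),
                 ref = character(), alt = character()),
      m, matrix(numeric(), 0, length(samples), dimnames = list(NULL, samples)), m
    ))
  }
  fmt <- v@gt[, "FORMAT"]
  for (field in c("GT", "GQ", "AD")) {
    missing_fmt <- !vapply(strsplit(fmt, ":", fixed = TRUE),
                           function(f) field %in% f, logical(1))
    if (any(missing_fmt)) {
      stop("FORMAT field '", field, "' missing on ", sum(missing_fmt),
           " record(s), first at line with POS=",
           fix[which(missing_fmt)[1], "POS"])
    }
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  ad <- vcfR::extract.gt(v, element = "AD")
  sites <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    id = ifelse(is.na(fix[, "ID"]), ".", fix[, "ID"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    stringsAsFactors = FALSE
  )
  rownames(gt) <- rownames(gq) <- rownames(ad) <- NULL
  vs <- variant_set(sites, gt, gq, ad)
  if (!check_site_order(sites$chrom, sites$pos)) {
    if (!allow_unsorted) {
      stop("VCF records are not sorted by (chromosome, position); ",
           "use allow_unsorted = TRUE to re-sort")
    }
    vs <- sort_sites(vs)
  }
  vs
}

#' Write a variant set as a plain-text VCF 4.2 file
#'
#' Emits GT:GQ:AD per sample. The output parses back through
#' [read_variants()] to an identical variant set (round-trip tested).
#'
#' @param vs a [variant_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(vs, path) {
  stopifnot(inherits(vs, "variant_set"))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=autozygr",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype Quality">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vs$samples), collapse = "\t")
  )
  n <- nrow(vs$sites)
  body <- character(n)
  if (n) {
    gq_chr <- ifelse(is.na(vs$gq), ".", format(vs$gq, trim = TRUE,
                                               scientific = FALSE))
    gt_chr <- ifelse(is.na(vs$gt), "./.", vs$gt)
    ad_chr <- ifelse(is.na(vs$ad), ".", vs$ad)
    calls <- matrix(paste(gt_chr, gq_chr, ad_chr, sep = ":"),
                    nrow = n)
    body <- paste(vs$sites$chrom, vs$sites$pos, vs$sites$id, vs$sites$ref,
                  vs$sites$alt, ".", ".", ".", "GT:GQ:AD",
                  apply(calls, 1L, paste, collapse = "\t"),
                  sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write ROH intervals as a BED file
#'
#' Internal 1-based closed intervals are converted to BED's 0-based
#' half-open convention (`start - 1`, `end`). Columns: chrom, start, end,
#' name (sample id or `"shared"`), score (number of supporting SNVs).
#'
#' @param intervals data frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive), `sample`, `n_snvs`, as produced by
#'   [detect_roh()] / [autozygome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roh_bed <- function(intervals, path) {
  intervals <- as.data.frame(intervals)
  need <- c("chrom", "start", "end", "sample", "n_snvs")
  if (!all(need %in% names(intervals))) {
    stop("intervals must have columns ", paste(need, collapse = ", "))
  }
  for (trk in split(intervals, intervals$sample)) {
    for (ch in split(trk, trk$chrom)) {
      ch <- ch[order(ch$start), ]
      if (nrow(ch) > 1L && any(ch$start[-1L] <= ch$end[-nrow(ch)])) {
        stop("overlapping intervals in track '", ch$sample[1], "' on ",
             ch$chrom[1])
      }
    }
  }
  lines <- c("#chrom\tstart\tend\tname\tscore")
  if (nrow(intervals)) {
    lines <- c(lines, paste(intervals$chrom,
                            format(intervals$start - 1L, scientific = FALSE,
                                   trim = TRUE),
                            format(intervals$end, scientific = FALSE,
                                   trim = TRUE),
                            intervals$sample, intervals$n_snvs, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read ROH intervals back from a BED file written by [write_roh_bed()]
#'
#' @param path BED file path.
#' @return Data frame with 1-based closed `start`/`end` columns.
#' @export
read_roh_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), sample = character(),
                      n_snvs = integer()))
  }
  parts <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(
    chrom = parts[, 1],
    start = as.integer(parts[, 2]) + 1L,
    end = as.integer(parts[, 3]),
    sample = parts[, 4],
    n_snvs = as.integer(parts[, 5]),
    stringsAsFactors = FALSE
  )
}

#' Write per-variant annotations as a long-format TSV
#'
#' One row per (variant, database) pair holding that database's allele
#' frequency and control heterozygote/homozygote counts; per-variant
#' fields (prediction labels, conservation score, phenotype match, known
#' disease link) are repeated on each of the variant's rows. Variants with
#' no database entries get a single row with `database = "."`.
#'
#' @param ann a named list of annotation bundles (see
#'   [annotation_bundle()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  rows <- lapply(names(ann), function(vid) {
    b <- ann[[vid]]
    dbs <- union(names(b$frequency),
                 union(names(b$het_count), names(b$hom_count)))
    if (!length(dbs)) dbs <- "."
    pred <- if (length(b$predictions)) {
      paste(names(b$predictions), b$predictions, sep = ":", collapse = ";")
    } else "."
    data.frame(
      variant = vid,
      database = dbs,
      frequency = vapply(dbs, function(d) db_value(b$frequency, d),
                         numeric(1)),
      n_het = vapply(dbs, function(d) db_value(b$het_count, d), numeric(1)),
      n_hom = vapply(dbs, function(d) db_value(b$hom_count, d), numeric(1)),
      predictions = pred,
      conservation = b$conservation %||% NA_real_,
      phenotype_match = b$phenotype_match,
      disease_link = b$disease_link %||% ".",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(variant = character(), database = character(),
                      frequency = numeric(), n_het = numeric(),
                      n_hom = numeric(), predictions = character(),
                      conservation = numeric(), phenotype_match = character(),
                      disease_link = character())
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an annotation TSV written by [write_annotations()]
#'
#' @param path TSV path.
#' @return Named list of annotation bundles.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = list(variant = "character",
                                             database = "character"))
  bundles <- lapply(split(tab, factor(tab$variant, levels = unique(tab$variant))),
                    function(rows) {
    dbs <- rows$database[rows$database != "."]
    keep <- rows$database != "."
    pred <- rows$predictions[1]
    predictions <- if (is.na(pred) || pred == ".") {
      stats::setNames(character(), character())
    } else {
      kv <- strsplit(strsplit(pred, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
      stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
    }
    annotation_bundle(
      frequency = stats::setNames(rows$frequency[keep], dbs),
      het_count = stats::setNames(rows$n_het[keep], dbs),
      hom_count = stats::setNames(rows$n_hom[keep], dbs),
      predictions = predictions,
      conservation = if (is.na(rows$conservation[1])) NULL
                     else rows$conservation[1],
      phenotype_match = rows$phenotype_match[1],
      disease_link = if (rows$disease_link[1] %in% c(".", NA)) NULL
                     else rows$disease_link[1]
    )
  })
  bundles[unique(tab$variant)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

db_value <- function(x, d) {
  if (d %in% names(x)) as.numeric(x[[d]]) else NA_real_
}
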