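p_default <- roh_params()

test_that("call classification applies the GQ/depth/allele-fraction rule", {
  expect_equal(classify_call("1/1", 30, "0,15", p_default), "HQ_HOM")
  expect_equal(classify_call("1/1", 19, "0,15", p_default), "LOW_QUALITY")
  # fraction 9/11 ~ 0.818 < 0.9
  expect_equal(classify_call("1/1", 25, "2,9", p_default), "LOW_QUALITY")
  expect_equal(classify_call("0/1", 50, "10,10", p_default), "HET")
  expect_equal(classify_call("./.", NA, NA, p_default), "MISSING")
  # homozygous reference also counts as a homozygote
  expect_equal(classify_call("0/0", 40, "20,0", p_default), "HQ_HOM")
  # depth just below threshold
  expect_equal(classify_call("1/1", 30, "0,9", p_default), "LOW_QUALITY")
  expect_error(classify_call("1/1", 30, "-1,15", p_default), "negative")
})

test_that("het quality gate only matters when het_min_gq is set", {
  strict <- roh_params(het_min_gq = 30)
  expect_equal(classify_call("0/1", 10, "5,5", p_default), "HET")
  expect_equal(classify_call("0/1", 10, "5,5", strict), "LOW_QUALITY")
  expect_equal(classify_call("0/1", 35, "5,5", strict), "HET")
})

test_that("multi-allelic homozygotes use the called allele's depth", {
  expect_equal(classify_call("2/2", 40, "0,1,19", p_default), "HQ_HOM")
  expect_equal(classify_call("2/2", 40, "0,10,10", p_default), "LOW_QUALITY")
})

test_that("detect_roh finds maximal interrupted runs of at least min_run", {
  # exactly four supporting SNVs, no het
  out <- detect_roh(c(1000, 2000, 3000, 4000), rep("HQ_HOM", 4), p_default)
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 1000)
  expect_equal(out$end, 4000)
  expect_equal(out$n_snvs, 4L)

  # three are not enough
  expect_equal(nrow(detect_roh(c(1, 2, 3) * 1000, rep("HQ_HOM", 3),
                               p_default)), 0L)

  # a het splits the run; only the 5-run after it survives
  cls <- c("HQ_HOM", "HQ_HOM", "HET", rep("HQ_HOM", 5))
  pos <- seq(1000, by = 1000, length.out = 8)
  out <- detect_roh(pos, cls, p_default)
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 4000)
  expect_equal(out$end, 8000)
  expect_equal(out$n_snvs, 5L)

  # LOW_QUALITY / MISSING sites neither break nor extend the run
  cls <- c("HQ_HOM", "LOW_QUALITY", "HQ_HOM", "MISSING", "HQ_HOM",
           "HQ_HOM", "LOW_QUALITY")
  pos <- seq(1000, by = 1000, length.out = 7)
  out <- detect_roh(pos, cls, p_default)
  expect_equal(out$start, 1000)
  expect_equal(out$end, 6000)
  expect_equal(out$n_snvs, 4L)

  expect_error(detect_roh(c(5, 1, 2, 3), rep("HQ_HOM", 4), p_default),
               "sorted")
})

test_that("a max_gap, when set, splits runs across long marker deserts", {
  pos <- c(1e3, 2e3, 3e3, 4e3, 5e6, 5e6 + (1:3) * 1e3)
  cls <- rep("HQ_HOM", 8)
  expect_equal(detect_roh(pos, cls, p_default)$n_snvs, 8L)
  gapped <- roh_params(max_gap = 1e5)
  out <- detect_roh(pos, cls, gapped)
  expect_equal(out$n_snvs, c(4L, 4L))
})

test_that("detect_roh matches the brute-force window oracle", {
  set.seed(101)
  for (i in 1:200) {
    ch <- random_classified_chromosome()
    got <- detect_roh(ch$pos, ch$class, p_default)
    want <- roh_oracle(ch$pos, ch$class, p_default$min_run)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$n_snvs, want$n_snvs)
  }
})

test_that("stricter quality parameters never enlarge the total ROH length", {
  set.seed(7)
  total_len <- function(vs_gt, vs_gq, vs_ad, pos, params) {
    cls <- classify_calls(vs_gt, vs_gq, vs_ad, params)
    t <- detect_roh(pos, cls[, 1], params)
    sum(t$end - t$start + 1)
  }
  for (i in 1:20) {
    n <- 120
    pos <- sort(sample.int(1e6, n))
    gt <- matrix(sample(c("1/1", "0/0", "0/1"), n, TRUE, c(.5, .25, .25)),
                 dimnames = list(NULL, "s"))
    gq <- matrix(sample(5:60, n, TRUE), dimnames = list(NULL, "s"))
    alt <- sample(5:30, n, TRUE)
    ref <- sample(0:6, n, TRUE)
    ad <- matrix(paste(ref, alt, sep = ","), dimnames = list(NULL, "s"))
    base <- total_len(gt, gq, ad, pos, roh_params())
    for (strict in list(roh_params(min_gq = 40),
                        roh_params(min_depth = 25),
                        roh_params(min_allele_fraction = 0.98),
                        roh_params(min_run = 8))) {
      expect_lte(total_len(gt, gq, ad, pos, strict), base)
    }
  }
})

test_that("intersect_roh performs length-filtered interval intersection", {
  a <- data.frame(chrom = "1", start = 1L, end = 2000000L, n_snvs = 10L,
                  sample = "a")
  # idempotence on identical sets
  same <- intersect_roh(list(a, a), p_default)
  expect_equal(same$start, 1L)
  expect_equal(same$end, 2000000L)

  # 0.5 Mb overlap is dropped under the 1 Mb floor
  b1 <- data.frame(chrom = "1", start = 1000000L, end = 2500000L,
                   n_snvs = 5L, sample = "x")
  b2 <- data.frame(chrom = "1", start = 2000000L, end = 4000000L,
                   n_snvs = 5L, sample = "y")
  expect_equal(nrow(intersect_roh(list(b1, b2), p_default)), 0L)
  # but kept with a lower floor
  expect_equal(nrow(intersect_roh(list(b1, b2),
                                  roh_params(min_shared_length = 4e5))), 1L)

  # disjoint sets give nothing
  c2 <- data.frame(chrom = "2", start = 1L, end = 3000000L, n_snvs = 5L,
                   sample = "z")
  expect_equal(nrow(intersect_roh(list(a, c2), p_default)), 0L)

  expect_error(intersect_roh(list(), p_default), "at least one")
})

test_that("intersection is commutative and associative over sample order", {
  set.seed(55)
  rand_track <- function() {
    s <- sort(sample.int(5e7, 6))
    data.frame(chrom = "1", start = s[c(1, 3, 5)], end = s[c(2, 4, 6)],
               n_snvs = 5L, sample = "t")
  }
  for (i in 1:10) {
    tr <- list(rand_track(), rand_track(), rand_track())
    ref <- intersect_roh(tr, p_default)
    for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
      expect_equal(intersect_roh(tr[perm], p_default), ref)
    }
  }
})

test_that("autozygome maps a simulated family and contains the planted site", {
  sim <- simulate_family(sim_config_noise_free(), seed = 202)
  az <- autozygome(sim$vs, sim$pedigree)
  expect_s3_class(az, "autozygome")
  expect_named(az$per_sample, c("II.1", "II.2"))
  # the planted variant lies inside the shared track
  expect_true(roh_containment_filter(sim$truth$planted$chrom,
                                     sim$truth$planted$pos, az$shared))
  # shared intervals are contained in every per-sample track
  for (s in names(az$per_sample)) {
    per <- az$per_sample[[s]]
    for (k in seq_len(nrow(az$shared))) {
      covered <- any(per$chrom == az$shared$chrom[k] &
                       per$start <= az$shared$start[k] &
                       per$end >= az$shared$end[k])
      expect_true(covered)
    }
  }
  # supporting counts on shared intervals are at least min_run
  expect_true(all(az$shared$n_snvs >= 4))
})

test_that("autozygome handles degenerate inputs", {
  sim <- simulate_family(sim_config_noise_free(), seed = 203)
  empty <- variant_set(sim$vs$sites[0, ], sim$vs$gt[0, , drop = FALSE],
                       sim$vs$gq[0, , drop = FALSE],
                       sim$vs$ad[0, , drop = FALSE])
  az <- autozygome(empty, sim$pedigree)
  expect_equal(nrow(az$shared), 0L)
  expect_true(all(vapply(az$per_sample, nrow, 0L) == 0L))

  # a single affected sample: shared = own track, length-filtered
  ped1 <- sim$pedigree
  ped1$affected[ped1$id == "II.2"] <- FALSE
  az1 <- autozygome(sim$vs, ped1)
  own <- az1$per_sample[["II.1"]]
  keep <- own$end - own$start + 1 >= 1e6
  expect_equal(az1$shared$start, own$start[keep])
  expect_equal(az1$shared$end, own$end[keep])

  ped_bad <- pedigree(
    id = c("father", "mother", "ghost", "II.2"),
    sex = c("male", "female", "male", "male"),
    affected = c(FALSE, FALSE, TRUE, TRUE),
    father = c(NA, NA, "father", "father"),
    mother = c(NA, NA, "mother", "mother"))
  expect_error(autozygome(sim$vs, ped_bad), "ghost")
})

test_that("only SNVs support runs; indels are transparent", {
  pos <- c(1000, 2000, 2500, 3000, 4000)
  sites <- data.frame(chrom = "1", pos = pos,
                      id = paste0("v", 1:5),
                      ref = c("A", "A", "AT", "A", "A"),
                      alt = c("T", "T", "A", "T", "T"))
  gt <- matrix("1/1", 5, 1, dimnames = list(NULL, "II.1"))
  gt[3, 1] <- "0/1" # het indel must not interrupt
  gq <- matrix(99, 5, 1, dimnames = list(NULL, "II.1"))
  ad <- matrix("0,30", 5, 1, dimnames = list(NULL, "II.1"))
  ad[3, 1] <- "15,15"
  vs <- variant_set(sites, gt, gq, ad)
  ped <- quartet_pedigree()
  ped$affected[ped$id == "II.2"] <- FALSE
  az <- autozygome(vs, ped, roh_params(min_shared_length = 1))
  expect_equal(az$per_sample[["II.1"]]$n_snvs, 4L)
  expect_equal(az$per_sample[["II.1"]]$start, 1000)
  expect_equal(az$per_sample[["II.1"]]$end, 4000)
})
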