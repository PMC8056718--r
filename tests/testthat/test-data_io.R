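test_that("long-table reading assembles dense matrices with missing pairs", {
  path <- write_tsv_fixture(c(
    "Feature\tCell\ttotal_reads\tmet_reads",
    "f1\tc1\t3\t1", "f1\tc2\t4\t2", "f2\tc1\t2\t0", "f2\tc2\t5\t3"))
  ds <- read_long_table(path)
  expect_equal(dim(ds$Y), c(2, 2))
  expect_false(anyNA(ds$Y))
  expect_equal(ds$Y["c2", "f2"], 3)
  expect_equal(ds$n["c1", "f1"], 3)

  path3 <- write_tsv_fixture(c(
    "Feature\tCell\ttotal_reads\tmet_reads",
    "f1\tc1\t3\t1", "f1\tc2\t4\t2", "f2\tc1\t2\t0"))
  ds3 <- read_long_table(path3)
  expect_true(is.na(ds3$Y["c2", "f2"]))
  expect_true(is.na(ds3$n["c2", "f2"]))
  expect_equal(sum(is.na(ds3$Y)), 1)
})

test_that("long-table reading rejects invalid rows with their position", {
  bad <- write_tsv_fixture(c(
    "Feature\tCell\ttotal_reads\tmet_reads",
    "f1\tc1\t3\t1", "f1\tc2\t3\t5"))
  expect_error(read_long_table(bad), "row 2")
  dup <- write_tsv_fixture(c(
    "Feature\tCell\ttotal_reads\tmet_reads",
    "f1\tc1\t3\t1", "f1\tc1\t4\t2"))
  expect_error(read_long_table(dup), "duplicate")
})

test_that("long-table writing round-trips the observed multiset", {
  path <- write_tsv_fixture(c(
    "Feature\tCell\ttotal_reads\tmet_reads",
    "f1\tc1\t3\t1", "f1\tc2\t4\t2", "f2\tc2\t5\t3"))
  ds <- read_long_table(path)
  out <- tempfile(fileext = ".tsv")
  write_long_table(ds, out)
  orig <- read.delim(path)
  back <- read.delim(out)
  key <- function(d) sort(do.call(paste, d))
  expect_identical(key(back), key(orig))
})

test_that("cpg call parsing supports both dialects and validates sites", {
  cov <- write_tsv_fixture(c("chr1\t101\t3\t1", "chr1\t150\t0\t2"))
  cs <- read_cpg_calls(cov, "coverage", cell_id = "c1")
  expect_equal(cs$records$position, c(101, 150))
  expect_equal(cs$records$met_reads, c(3, 0))
  expect_equal(cs$records$unmet_reads, c(1, 2))

  rate <- write_tsv_fixture(c("chr1\t101\t1", "chr1\t102\t0"))
  cr <- read_cpg_calls(rate, "rate", cell_id = "c1")
  expect_equal(cr$records$met_reads, c(1, 0))
  expect_equal(cr$records$unmet_reads, c(0, 1))

  zero <- write_tsv_fixture(c("chr1\t101\t0\t0"))
  expect_error(read_cpg_calls(zero, "coverage"), "uncovered site")
  neg <- write_tsv_fixture(c("chr1\t101\t-1\t2"))
  expect_error(read_cpg_calls(neg, "coverage"), "negative")
  frac <- write_tsv_fixture(c("chr1\t10.5\t1\t1"))
  expect_error(read_cpg_calls(frac, "coverage"), "coordinate")
})

test_that("window annotations tile chromosomes and apply the clipping rule", {
  ann <- make_feature_annotations(windows = list(
    chrom_sizes = c(chrA = 60000), width = 20000, step = 20000))
  expect_equal(nrow(ann), 3)
  expect_equal(ann$start, c(0, 20000, 40000))
  expect_equal(ann$end, c(20000, 40000, 60000))
  # clipped remainder kept when >= half the nominal width
  ann2 <- make_feature_annotations(windows = list(
    chrom_sizes = c(chrA = 50000), width = 20000, step = 20000,
    min_fraction = 0.5))
  expect_equal(ann2$end, c(20000, 40000, 50000))
  # and discarded when shorter
  ann3 <- make_feature_annotations(windows = list(
    chrom_sizes = c(chrA = 45000), width = 20000, step = 20000,
    min_fraction = 0.5))
  expect_equal(nrow(ann3), 2)
  # non-overlapping tiling covers the chromosome before clipping
  expect_true(all(ann$start[-1] == head(ann$end, -1)))
})

test_that("promoter annotations are centered windows around the TSS", {
  tss <- data.frame(chrom = "chr1", tss = 5000, strand = "+", gene_id = "g1")
  ann <- make_feature_annotations(promoters = list(tss = tss, flank = 2000))
  expect_equal(ann$start, 3000)
  expect_equal(ann$end, 7000)
  expect_error(make_feature_annotations(promoters = list(tss = tss, flank = 0)),
               "positive")
  expect_error(make_feature_annotations(), "exactly one")
})

test_that("aggregation counts covered sites with coordinate conversion", {
  rec <- data.frame(chrom = "chr1", position = c(101, 102, 105),
                    met_reads = c(2, 0, 1), unmet_reads = c(0, 1, 0))
  calls <- list(structure(list(cell_id = "c1", records = rec),
                          class = "cpg_call_set"))
  ann <- data.frame(feature_id = "fA", chrom = "chr1", start = 100,
                    end = 106, strand = "*")
  ds <- aggregate_to_features(calls, ann)
  expect_equal(ds$n["c1", "fA"], 3)
  expect_equal(ds$Y["c1", "fA"], 2)
})

test_that("aggregation respects the half-open end and the tie rule", {
  # a 1-based site whose 0-based coordinate equals the exclusive end is the
  # first base outside [start, end): position 106 (0-based 105) vs end 105
  rec <- data.frame(chrom = "chr1", position = c(106, 105),
                    met_reads = c(1, 1), unmet_reads = c(0, 0))
  calls <- list(structure(list(cell_id = "c1", records = rec),
                          class = "cpg_call_set"))
  ann <- data.frame(feature_id = "fA", chrom = "chr1", start = 100,
                    end = 105, strand = "*")
  ds <- aggregate_to_features(calls, ann)
  expect_equal(ds$n["c1", "fA"], 1) # only position 105 (0-based 104) inside
  ann2 <- ann; ann2$end <- 106
  ds2 <- aggregate_to_features(calls, ann2)
  expect_equal(ds2$n["c1", "fA"], 2) # position 106 = 0-based 105 now inside
  # tied reads drop the site from both counts
  rec3 <- data.frame(chrom = "chr1", position = c(101, 102),
                     met_reads = c(2, 3), unmet_reads = c(2, 0))
  calls3 <- list(structure(list(cell_id = "c1", records = rec3),
                           class = "cpg_call_set"))
  ds3 <- aggregate_to_features(calls3, ann2)
  expect_equal(ds3$n["c1", "fA"], 1)
  expect_equal(ds3$Y["c1", "fA"], 1)
})

test_that("aggregation over a tiling conserves covered sites per cell", {
  set.seed(42)
  pos <- sort(sample(1:4000, 120))
  rec <- data.frame(chrom = "chr1", position = pos,
                    met_reads = rbinom(120, 3, 0.4), unmet_reads = 0)
  rec$unmet_reads <- 3 - rec$met_reads
  keep <- rec$met_reads != rec$unmet_reads
  calls <- list(structure(list(cell_id = "c1", records = rec),
                          class = "cpg_call_set"))
  ann <- make_feature_annotations(windows = list(
    chrom_sizes = c(chr1 = 4000), width = 1000, step = 1000))
  ds <- aggregate_to_features(calls, ann)
  expect_equal(sum(ds$n, na.rm = TRUE), sum(keep))
  expect_error(aggregate_to_features(calls, ann[0, ]), "empty annotation")
})

test_that("dataset invariants are enforced", {
  Y <- matrix(c(1, NA), 1)
  n <- matrix(c(2, 3), 1)
  expect_error(methylation_dataset(Y, n), "missing at exactly")
  expect_error(methylation_dataset(matrix(4), matrix(3)), "0 <= Y <= n")
  expect_error(methylation_dataset(matrix(1), matrix(1),
                                   X = matrix(2, 1, 1)), "ones")
  expect_silent(validate_dataset(toy_dataset()))
})
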