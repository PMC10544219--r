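sel_df <- function(starts, ends, gene = "g1", class = "exon",
                   substrate = 100, edits = 5, strand = "+") {
  n <- length(starts)
  data.frame(window_id = sprintf("%s:%s:%d", gene, class, seq_len(n)),
             chrom = "c1", start = starts, end = ends, strand = strand,
             gene_id = gene, region_class = class,
             substrate_instances = rep_len(substrate, n),
             edit_instances = rep_len(edits, n),
             distinct_edited_positions = rep_len(2L, n),
             read_depth = 50L,
             edit_fraction = rep_len(edits, n) / rep_len(substrate, n),
             p_adj = 0.01, stringsAsFactors = FALSE)
}

test_that("window selection thresholds adjusted p-values", {
  df <- sel_df(c(1, 100), c(30, 130))
  df$p_adj <- c(0.05, 0.2)
  expect_equal(select_windows(df, 0.1)$window_id, df$window_id[1])
  expect_error(select_windows(df, 0), "alpha")
  expect_error(select_windows(df, 1.5), "alpha")
  expect_identical(eval(formals(select_windows)$alpha), 0.1)
  # stricter alpha selects a subset
  set.seed(3)
  df2 <- sel_df(seq(1, 2000, by = 40), seq(30, 2029, by = 40))
  df2$p_adj <- runif(nrow(df2), 0, 0.2)
  s_strict <- select_windows(df2, 0.01)$window_id
  s_loose <- select_windows(df2, 0.1)$window_id
  expect_true(all(s_strict %in% s_loose))
})

test_that("windows merge across gaps up to the merge distance", {
  # BED-style gaps: [0,30) and [40,70) have a 10 bp gap -> one cluster
  m1 <- merge_windows(sel_df(c(1, 41), c(30, 70)), 15)
  expect_length(m1, 1L)
  expect_equal(BiocGenerics::start(m1), 1L)
  expect_equal(BiocGenerics::end(m1), 70L)
  expect_equal(m1$substrate_instances, 200)
  expect_equal(m1$edit_instances, 10L)
  expect_equal(m1$edit_fraction, 0.05)

  # a 20 bp gap stays split
  m2 <- merge_windows(sel_df(c(1, 51), c(30, 80)), 15)
  expect_length(m2, 2L)

  # adjacent windows (gap 0) merge
  m3 <- merge_windows(sel_df(c(1, 31), c(30, 60)), 15)
  expect_length(m3, 1L)
  expect_equal(BiocGenerics::end(m3), 60L)

  # merging never crosses gene or region class
  df <- rbind(sel_df(c(1, 41), c(30, 70), gene = "gA"),
              sel_df(c(101, 141), c(130, 170), gene = "gB"))
  df <- rbind(df, sel_df(c(201, 241), c(230, 270), gene = "gA",
                         class = "intron"))
  m4 <- merge_windows(df, 1000)
  expect_length(m4, 3L)
  expect_identical(eval(formals(merge_windows)$merge_distance), 15L)
})

test_that("merging equals a transitive-closure oracle on random inputs", {
  set.seed(7)
  for (i in 1:100) {
    df <- random_window_set(sample(2:25, 1))
    d <- sample(c(0L, 5L, 15L, 40L), 1)
    got <- merge_windows(df, d)
    want <- merge_oracle(df, d)[[1]]
    expect_length(got, length(want))
    expect_equal(BiocGenerics::start(got),
                 vapply(want, `[[`, numeric(1), "start"))
    expect_equal(BiocGenerics::end(got),
                 vapply(want, `[[`, numeric(1), "end"))
    expect_equal(got$substrate_instances,
                 vapply(want, `[[`, numeric(1), "substrate"))
    expect_equal(as.numeric(got$edit_instances),
                 vapply(want, `[[`, numeric(1), "edits"))
    # clusters are separated by more than the merge distance
    if (length(got) > 1L) {
      gaps <- BiocGenerics::start(got)[-1] -
        BiocGenerics::end(got)[-length(got)] - 1L
      expect_true(all(gaps > d))
    }
    # every window lands in exactly one cluster
    members <- unlist(strsplit(got$member_window_ids, ","))
    expect_setequal(members, df$window_id)
    expect_equal(length(members), nrow(df))
  }
})

test_that("pooled cluster counts equal a re-aggregation over member spans", {
  cfg <- simulation_config(n_genes = 6, n_foci = 6, seed = 17)
  ds <- generate_dataset(cfg)
  win <- make_windows(ds$models)
  st <- aggregate_windows(win, ds$sites, ds$coverage, cfg$conversion,
                          ds$reference)
  tests <- test_windows(st, fit_background(st))
  cl <- merge_windows(select_windows(tests, 0.1), 15)
  expect_gt(length(cl), 0L)
  for (i in seq_along(cl)) {
    ids <- strsplit(cl$member_window_ids[i], ",")[[1]]
    members <- win[win$window_id %in% ids]
    re <- aggregate_windows(members, ds$sites, ds$coverage,
                            cfg$conversion, ds$reference)
    expect_equal(sum(re$substrate_instances), cl$substrate_instances[i])
    expect_equal(sum(re$edit_instances), cl$edit_instances[i])
  }
})

test_that("negative-binomial scores match hand-computed values", {
  cl <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(1, 101), width = 30),
                               strand = "+")
  cl$cluster_id <- c("a", "b"); cl$gene_id <- "g"; cl$region_class <- "exon"
  cl$n_windows <- 1L; cl$member_window_ids <- "w"
  cl$substrate_instances <- c(2, 5)
  cl$edit_instances <- c(1L, 0L)
  cl$distinct_edited_positions <- c(1L, 0L)
  cl$edit_fraction <- c(0.5, 0)

  model <- structure(list(p_bar = 0.5, n_clusters = 2),
                     class = "nb_score_model")
  s <- score_clusters(cl, model)$score
  expect_equal(s[1], 0.75)           # P(Y <= 1), r = 1, p = 0.5
  model2 <- structure(list(p_bar = 0.1, n_clusters = 2),
                      class = "nb_score_model")
  s2 <- score_clusters(cl, model2)$score
  expect_equal(s2[2], 0.9^5)         # P(Y <= 0), r = 5, p = 0.1

  # fully edited clusters score 1
  cl$edit_instances <- c(2L, 5L); cl$edit_fraction <- 1
  expect_equal(score_clusters(cl, model)$score, c(1, 1))

  # score is non-decreasing in edit count at fixed substrate
  n <- 200
  scores <- vapply(0:n, function(k) {
    g <- cl[1]
    g$substrate_instances <- n; g$edit_instances <- k
    score_clusters(g, model2)$score
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
  expect_gt(scores[n + 1], scores[1])
})

test_that("the score model is the clamped mean cluster fraction", {
  cl <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(1, 101), width = 30))
  cl$edit_fraction <- c(0.1, 0.3)
  m <- fit_score_model(cl)
  expect_equal(m$p_bar, 0.2)
  cl$edit_fraction <- c(0, 0)
  expect_equal(fit_score_model(cl)$p_bar, 1e-9)
  expect_warning(m1 <- fit_score_model(cl[1]), "fewer than two")
  expect_null(m1)
  # scoring without a model reports missing scores
  cl1 <- cl[1]; cl1$substrate_instances <- 10; cl1$edit_instances <- 1L
  expect_warning(s <- score_clusters(cl1), "fewer than two")
  expect_true(is.na(s$score))
})

test_that("efficiency score trades sites per cluster against footprint", {
  cl <- GenomicRanges::GRanges(
    "c1", IRanges::IRanges(c(1, 201), width = c(100, 300)))
  cl$distinct_edited_positions <- c(3L, 5L)
  expect_equal(efficiency_score(cl), 4 / 200)
  one <- cl[1]; one$distinct_edited_positions <- 2L
  expect_equal(efficiency_score(one), 0.02)
  # doubling lengths at fixed sites halves the score
  cl2 <- GenomicRanges::GRanges(
    "c1", IRanges::IRanges(c(1, 401), width = c(200, 600)))
  cl2$distinct_edited_positions <- c(3L, 5L)
  expect_equal(efficiency_score(cl2), efficiency_score(cl) / 2)
  expect_error(efficiency_score(cl[0]), "zero clusters")
  expect_equal(efficiency_score(cl, variant = "total_footprint"), 4 / 400)
})

test_that("replicate intersection keeps clusters present in all sets", {
  g <- function(s, e, strand = "+") GenomicRanges::GRanges(
    "c1", IRanges::IRanges(s, e), strand = strand)
  set1 <- g(1, 70)
  expect_length(intersect_replicates(list(set1, g(51, 120), g(61, 65))), 1L)
  expect_length(intersect_replicates(list(set1, g(200, 300), g(61, 65))), 0L)
  # strand must match
  expect_length(intersect_replicates(list(set1, g(51, 120, "-"))), 0L)
  # identical sets are the identity
  cfg <- simulation_config(n_genes = 3, n_foci = 3, seed = 2)
  ds <- generate_dataset(cfg)
  expect_identical(
    length(intersect_replicates(list(ds$foci, ds$foci, ds$foci))),
    length(ds$foci))
  expect_error(intersect_replicates(list(set1)), "two replicate")
})

test_that("condition comparison flags directionally consistent shifts", {
  a <- rbind(c(0.1, 0.1), c(0.2, 0.2), c(0.1, 0.3))
  b <- rbind(c(0.2, 0.2), c(0.2, 0.2), c(0.2, 0.2))
  cmp <- compare_conditions(a, b)
  expect_equal(cmp$ratio, c(0.5, 1, 1))
  expect_equal(cmp$consistent, c(TRUE, FALSE, FALSE))
  expect_true(all(cmp$defined))
  cmp0 <- compare_conditions(rbind(c(0.1, 0.1)), rbind(c(0, 0)))
  expect_false(cmp0$defined)
  expect_true(is.na(cmp0$ratio))
})
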