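test_that("expression study round-trips through TSV and validates inputs", {
  m <- matrix(c(10.5, 20.25, 30.125, 40, 50, 60, 7, 8, 9, 1.5, 2.5, 3.5),
              nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3", "s4")))
  design <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                       donor = c("d1", "d1", "d2", "d2"),
                       condition = c("medium", "IgG", "medium", "IgG"),
                       replicate = 1L)
  study <- expression_study(m, design)
  expect_equal(study_genes(study), c("g1", "g2", "g3"))
  expect_equal(ncol(study$intensities), 4L)

  mp <- tempfile(fileext = ".tsv"); sp <- tempfile(fileext = ".tsv")
  write_expression_study(study, mp, sp)
  back <- read_expression_study(mp, sp)
  expect_equal(back$intensities, study$intensities, tolerance = 1e-12)
  expect_equal(back$design, study$design)
  # idempotence of a second round trip
  write_expression_study(back, mp, sp)
  again <- read_expression_study(mp, sp)
  expect_identical(again$intensities, back$intensities)

  # validation errors name offenders
  expect_error(expression_study(m, design[-2, ]), "s2")
  bad <- design; bad$condition[1] <- "mystery"
  expect_error(expression_study(m, bad), "mystery")
  writeLines(c("gene\ts1\ts2\ts3\ts4", "g1\t1\toops\t3\t4"), mp)
  expect_error(read_expression_study(mp, sp), "oops")
})

test_that("condition synonyms are canonicalized and the floor is applied", {
  expect_equal(canonical_condition(c("Media", "IgG+IL12", "il-12", "FCR")),
               c("medium", "IgG_IL12", "IL12", "IgG"))
  m <- matrix(c(0.2, 5), nrow = 2, dimnames = list(c("g1", "g2"), "s1"))
  d <- data.frame(sample_id = "s1", donor = "d1", condition = "medium",
                  replicate = 1L)
  expect_equal(unname(expression_study(m, d)$intensities[, 1]), c(1, 5))
  expect_equal(unname(expression_study(m, d, floor = -Inf)$intensities[, 1]),
               c(0.2, 5))
})

test_that("collapse_replicates averages in linear scale per (donor, condition)", {
  # two hand values plus a pass-through singleton
  m <- matrix(c(100, 102, 250), nrow = 1,
              dimnames = list("g1", c("a1", "a2", "b1")))
  d <- data.frame(sample_id = c("a1", "a2", "b1"),
                  donor = c("d1", "d1", "d2"),
                  condition = c("medium", "medium", "medium"),
                  replicate = c(1L, 2L, 1L))
  cs <- collapse_replicates(expression_study(m, d))
  expect_equal(sort(unname(cs$intensities[1, ])), c(101, 250))
  expect_true(all(cs$design$replicate == 1L))

  # 8 donors x 4 conditions x 2 replicates against a group-by oracle
  set.seed(11)
  sim <- simulate_expression(simulation_config(n_genes = 20, seed = 11))
  st <- sim$study
  cs <- collapse_replicates(st)
  expect_equal(ncol(cs$intensities), 32L)
  cell <- paste(st$design$donor, st$design$condition, sep = ".")
  for (g in c(1L, 7L, 20L)) {
    oracle <- tapply(st$intensities[g, ], cell, mean)
    expect_equal(unname(cs$intensities[g, names(oracle)]),
                 as.numeric(oracle))
  }
  # collapsing preserves the per-cell mean of every gene exactly
  expect_equal(rowMeans(cs$intensities), rowMeans(st$intensities),
               tolerance = 1e-12)
})

test_that("replicate concordance is the squared Pearson correlation", {
  set.seed(3)
  base <- matrix(rlnorm(30 * 2, 5, 1), nrow = 30)
  m <- cbind(base[, 1], base[, 1], base[, 2], 2 * base[, 2] + 7)
  dimnames(m) <- list(sprintf("g%d", 1:30), c("a1", "a2", "b1", "b2"))
  d <- data.frame(sample_id = colnames(m),
                  donor = c("d1", "d1", "d2", "d2"),
                  condition = "medium", replicate = c(1L, 2L, 1L, 2L))
  rc <- replicate_concordance(expression_study(m, d))
  expect_equal(rc$r_squared, c(1, 1))  # identical and affine replicates
  expect_equal(attr(rc, "mean_r_squared"), 1)

  # noisy duplicates match the textbook correlation formula
  x <- base[, 1]; y <- base[, 1] + rnorm(30, 0, 20)
  m2 <- cbind(x, y); dimnames(m2) <- list(rownames(m), c("c1", "c2"))
  d2 <- data.frame(sample_id = c("c1", "c2"), donor = "d1",
                   condition = "medium", replicate = 1:2)
  rc2 <- replicate_concordance(expression_study(m2, d2, floor = -Inf))
  manual <- (sum((x - mean(x)) * (y - mean(y))) /
               sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))^2
  expect_equal(rc2$r_squared, manual, tolerance = 1e-12)

  # wrong replicate count is skipped with a warning; zero variance gives NA
  m3 <- cbind(m2, c3 = x)
  d3 <- rbind(d2, data.frame(sample_id = "c3", donor = "d1",
                             condition = "medium", replicate = 3L))
  expect_warning(rc3 <- replicate_concordance(expression_study(m3, d3)),
                 "3 replicates")
  expect_equal(nrow(rc3), 0L)
  m4 <- cbind(c1 = rep(5, 30), c2 = x)
  rownames(m4) <- rownames(m)
  rc4 <- replicate_concordance(expression_study(m4, d2))
  expect_true(is.na(rc4$r_squared))
})

test_that("annotation catalogs parse from GMT and tsv2col equivalently", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("catA\tdesc A\tg1\tg2", "catB\tdesc B\tg2\tg3"), gmt)
  cat_g <- read_annotations(gmt, "gmt")
  expect_equal(cat_g$categories$catA, c("g1", "g2"))
  expect_equal(cat_g$universe, c("g1", "g2", "g3"))

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tcategory", "g1\tcatA", "g2\tcatA", "g2\tcatB",
               "g3\tcatB"), tsv)
  cat_t <- read_annotations(tsv, "tsv2col")
  expect_equal(cat_t$categories, cat_g$categories)

  # duplicate names merge with a warning; empty file errors
  writeLines(c("catA\td\tg1", "catA\td\tg9"), gmt)
  expect_warning(merged <- read_annotations(gmt, "gmt"), "catA")
  expect_equal(merged$categories$catA, c("g1", "g9"))
  writeLines(character(0), gmt)
  expect_error(read_annotations(gmt, "gmt"), "empty")
})

test_that("a 50-category synthetic catalog round-trips through GMT", {
  sim <- simulate_expression(simulation_config(n_genes = 300, seed = 5))
  catalog <- simulate_annotations(sim$truth, n_categories = 50, seed = 5)
  path <- tempfile(fileext = ".gmt")
  write_gmt(catalog, path)
  back <- read_annotations(path, "gmt", universe = catalog$universe)
  expect_identical(back$categories, catalog$categories)
  expect_identical(back$universe, catalog$universe)
})

test_that("edge tables parse, default, and drop self-loops", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\tweight\tedge_type\tdirected",
               "a\tb\t1.0\tcoexp\t1",
               "a\ta\t1\tx\t1",
               "b\tc\t2.5\tpath\t0"), p)
  expect_warning(et <- read_edge_table(p), "self-loop")
  expect_equal(nrow(et), 2L)
  expect_equal(et$directed, c(TRUE, FALSE))

  # weight column absent -> default 1.0
  writeLines(c("source\ttarget", "x\ty"), p)
  expect_equal(read_edge_table(p)$weight, 1.0)

  writeLines(c("source\ttarget\tweight", "x\ty\t-2"), p)
  expect_error(read_edge_table(p), "non-negative")
  writeLines(c("source\ttarget\tdirected", "x\ty\tmaybe"), p)
  expect_error(read_edge_table(p), "directed")

  # row count preserved minus self-loops on a synthetic 100-row file
  set.seed(21)
  df <- data.frame(source = sample(letters[1:8], 100, TRUE),
                   target = sample(letters[1:8], 100, TRUE),
                   weight = runif(100), edge_type = "x", directed = 1)
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  n_loops <- sum(df$source == df$target)
  et <- if (n_loops) suppressWarnings(read_edge_table(p)) else
    read_edge_table(p)
  expect_equal(nrow(et), 100L - n_loops)
})

test_that("Pajek export writes vertices then arcs with 1-based indices", {
  edges <- edge_table(data.frame(source = c("a", "b"), target = c("b", "c"),
                                 weight = c(1, 2.5), edge_type = "x",
                                 directed = TRUE))
  net <- build_network(c("a", "b", "c"), edges)
  path <- tempfile(fileext = ".net")
  write_pajek(net, path)
  lines <- readLines(path)
  expect_equal(lines[1], "*Vertices 3")
  expect_equal(lines[2], "1 \"a\"")
  expect_equal(lines[5], "*Arcs")
  expect_setequal(lines[6:7], c("1 2 1", "2 3 2.5"))
})
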