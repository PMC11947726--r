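test_that("breed profiles standardize to the closed-form z-scores", {
  # one gene with breed means exactly 1, 2, 3 and one constant gene
  m <- cbind(matrix(1, 2, 4), matrix(2, 2, 4), matrix(3, 2, 4))
  m[2, ] <- 5
  m <- rbind(m, 0.5)   # third gene, constant
  rownames(m) <- c("G1", "G2", "G3")
  breeds <- rep(c("AWB", "JH", "DU"), each = 4)
  prof <- breed_profile(m, breeds)
  expect_equal(unname(prof["G1", ]), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-12)
  expect_false("G2" %in% rownames(prof))      # constant genes dropped
  expect_true(all(c("G2", "G3") %in% attr(prof, "dropped")))
  expect_equal(unname(rowMeans(prof)), rep(0, nrow(prof)), tolerance = 1e-12)
  pop_sd <- sqrt(rowMeans((prof - rowMeans(prof))^2))
  expect_equal(unname(pop_sd), rep(1, nrow(prof)), tolerance = 1e-12)
  expect_error(breed_profile(m, rep(c("AWB", "JH"), each = 6)), "missing breed")
})

test_that("the fuzzifier formula matches an independent evaluation", {
  # independent inline evaluation of the empirical estimate
  N <- 2000; D <- 3
  expected <- 1 + (1418 / N + 22.05) * D^(-2) +
    (12.33 / N + 0.243) * D^(-0.0406 * log(N) - 0.1134)
  expect_equal(estimate_fuzzifier(2000, 3), expected, tolerance = 1e-6)
  grid <- expand.grid(N = c(10, 100, 1000, 10000), D = 2:10)
  m <- mapply(estimate_fuzzifier, grid$N, grid$D)
  expect_true(all(m > 1))
  for (N in unique(grid$N)) {
    ms <- m[grid$N == N][order(grid$D[grid$N == N])]
    expect_true(all(diff(ms) < 0))   # decreasing in D at fixed N
  }
  expect_error(estimate_fuzzifier(1, 3), ">= 2")
})

test_that("fuzzy c-means obeys its update-rule invariants", {
  set.seed(1)
  x <- rbind(matrix(rnorm(60, 0, 0.3), 20, 3),
             matrix(rnorm(60, 3, 0.3), 20, 3))
  rownames(x) <- sprintf("g%02d", 1:40)
  fit <- fuzzy_cmeans(x, centers = 3, m = 1.5, seed = 2)
  expect_true(fit$converged)
  expect_equal(unname(rowSums(fit$membership)), rep(1, 40), tolerance = 1e-9)
  expect_true(all(fit$membership >= 0 & fit$membership <= 1))
  expect_true(all(diff(fit$objective) <= 1e-8))   # non-increasing objective
  # fuzzifier limit: a large m drives the membership update toward 1/c
  # (tested on one update step; at extreme m the full alternating scheme
  # degenerates numerically, in this and in reference implementations)
  flat <- suppressWarnings(
    fuzzy_cmeans(x, centers = 4, m = 1000, seed = 3, max_iter = 1))
  expect_lt(max(abs(flat$membership - 0.25)), 0.05)
  expect_error(fuzzy_cmeans(x, centers = 40), "smaller")
})

test_that("near-crisp c-means matches the exhaustive 2-partition oracle", {
  set.seed(4)
  x <- rbind(matrix(rnorm(12, 0, 0.15), 4, 3),
             matrix(rnorm(12, 2.5, 0.15), 4, 3))
  rownames(x) <- sprintf("p%d", 1:8)
  fit <- fuzzy_cmeans(x, centers = 2, m = 1.05, seed = 5)
  # oracle: best 2-partition of 8 points by within-cluster sum of squares
  best <- NULL; best_ss <- Inf
  for (code in 1:(2^7 - 1)) {
    assign <- c(0, as.integer(intToBits(code))[1:7])
    ss <- 0
    for (g in 0:1) {
      pts <- x[assign == g, , drop = FALSE]
      if (nrow(pts)) ss <- ss + sum(sweep(pts, 2, colMeans(pts))^2)
    }
    if (ss < best_ss) { best_ss <- ss; best <- assign }
  }
  expect_equal(ari(fit$hard, best), 1)
  expect_equal(ari(fit$hard, rep(1:2, each = 4)), 1)
})

test_that("the hand-written optimizer agrees with an independent c-means", {
  set.seed(6)
  x <- rbind(matrix(rnorm(90, 0, 0.4), 30, 3),
             matrix(rnorm(90, 3, 0.4), 30, 3))
  rownames(x) <- sprintf("g%02d", 1:60)
  fit <- fuzzy_cmeans(x, centers = 2, m = 1.8, seed = 7)
  ref <- e1071::cmeans(x, centers = 2, m = 1.8, iter.max = 500)
  # same partition and matching centroids up to cluster relabeling
  expect_equal(ari(fit$hard, ref$cluster), 1)
  perm <- if (sum((fit$centers[1, ] - ref$centers[1, ])^2) <
              sum((fit$centers[1, ] - ref$centers[2, ])^2)) 1:2 else 2:1
  expect_equal(unname(fit$centers), unname(ref$centers[perm, ]),
               tolerance = 1e-3)
})

test_that("minimum centroid distance flags redundant cluster numbers", {
  set.seed(8)
  x <- rbind(matrix(rnorm(150, 0, 0.2), 50, 3),
             matrix(rnorm(150, 3, 0.2), 50, 3))
  rownames(x) <- sprintf("g%03d", 1:100)
  tab <- min_centroid_distance(x, m = 1.5, c_range = 2:5, seed = 9)
  expect_true(all(tab$dmin >= 0))
  expect_gt(tab$dmin[tab$c == 2], 3 * tab$dmin[tab$c == 3])
  dup <- matrix(rep(c(1, 0, -1), each = 30), 30, 3) +
    matrix(rnorm(90, 0, 1e-6), 30, 3)
  rownames(dup) <- sprintf("d%02d", 1:30)
  tab2 <- min_centroid_distance(dup, m = 1.3, c_range = 2:3, seed = 10)
  expect_true(all(tab2$dmin < 0.1))
  expect_error(min_centroid_distance(x, c_range = 1:3), "c_range")
})

# build a synthetic fuzzy_cmeans fit for rule tests
fake_fit <- function(centers, genes_per_cluster = 1, memb = 0.9) {
  cc <- nrow(centers)
  n <- cc * genes_per_cluster
  membership <- matrix((1 - memb) / (cc - 1), n, cc)
  hard <- rep(seq_len(cc), each = genes_per_cluster)
  membership[cbind(seq_len(n), hard)] <- memb
  rownames(membership) <- sprintf("gene%02d", seq_len(n))
  structure(list(centers = centers, membership = membership, hard = hard,
                 m = 2, objective = 1, converged = TRUE),
            class = "fuzzy_cmeans")
}

deg_table <- function(genes, deg_genes, direction) {
  data.frame(gene = genes,
             log2fc = ifelse(genes %in% deg_genes,
                             ifelse(direction == "up", 2, -2), 0),
             p = 0.001, padj = 0.001,
             direction = ifelse(genes %in% deg_genes, direction, "up"),
             deg = genes %in% deg_genes, stringsAsFactors = FALSE)
}

test_that("pattern rules intersect centroid shapes with DEG evidence", {
  centers <- rbind(c(-1.22, 0, 1.22),      # increasing
                   c(-0.5, 1.2, -0.7),     # JH-high
                   c(0.5, -1.2, 0.7),      # JH-low
                   c(1.22, 0, -1.22))      # decreasing
  fit <- fake_fit(centers)
  genes <- rownames(fit$membership)
  # gene 1 up-DEG JH vs AWB only -> type1
  pa <- classify_patterns(fit, deg_table(genes, genes[1], "up"),
                          deg_table(genes, character(0), "up"))
  expect_equal(pa$pattern, c("type1", "none", "none", "none"))
  # up in both comparisons: JH-high cluster gene becomes type2
  pb <- classify_patterns(fit, deg_table(genes, genes, "up"),
                          deg_table(genes, genes, "up"))
  expect_equal(pb$pattern[2], "type2")
  # down in both: type3; decreasing cluster with JH-down evidence: type4
  pc <- classify_patterns(fit, deg_table(genes, genes, "down"),
                          deg_table(genes, genes, "down"))
  expect_equal(pc$pattern[3], "type3")
  expect_equal(pc$pattern[4], "type4")
  # high membership without DEG evidence stays unclassified
  pd <- classify_patterns(fit, deg_table(genes, character(0), "up"),
                          deg_table(genes, character(0), "up"))
  expect_true(all(pd$pattern == "none"))
  # tied centroid -> no class
  fit_tie <- fake_fit(rbind(c(0, 0, 0), c(-1.22, 0, 1.22)))
  pe <- classify_patterns(fit_tie, deg_table(rownames(fit_tie$membership),
                                             rownames(fit_tie$membership),
                                             "up"),
                          deg_table(rownames(fit_tie$membership),
                                    character(0), "up"))
  expect_equal(pe$pattern[1], "none")
  # patterns are exclusive and exhaustive
  expect_true(all(pe$pattern %in% c("type1", "type2", "type3", "type4",
                                    "none")))
})

test_that("planted expression patterns are recovered through the pipeline", {
  set.seed(11)
  shapes <- list(type1 = c(-1, 0, 1), type2 = c(-0.7, 1.4, -0.7),
                 type3 = c(0.7, -1.4, 0.7), type4 = c(1, 0, -1))
  rows <- list(); truth <- character(0); da_dir <- character(0)
  for (p in names(shapes)) {
    block <- matrix(rep(shapes[[p]], each = 100), 100, 3) +
      matrix(rnorm(300, 0, 0.2), 100, 3)
    rows[[p]] <- block
    truth <- c(truth, rep(p, 100))
  }
  null_block <- matrix(rnorm(600 * 3, 0, 1), 600, 3)
  x <- rbind(do.call(rbind, rows), null_block)
  truth <- c(truth, rep("none", 600))
  x <- (x - rowMeans(x)) / sqrt(rowMeans((x - rowMeans(x))^2))
  rownames(x) <- sprintf("g%04d", seq_len(nrow(x)))
  genes <- rownames(x)

  # DEG evidence consistent with each planted pattern; null genes get
  # random spurious calls so the intersection rule is exercised
  da <- rep("ns", nrow(x)); dd <- rep("ns", nrow(x))
  da[truth == "type1"] <- "up"
  da[truth == "type2"] <- "up"; dd[truth == "type2"] <- "up"
  da[truth == "type3"] <- "down"; dd[truth == "type3"] <- "down"
  da[truth == "type4"] <- "down"
  spurious <- truth == "none" & runif(length(truth)) < 0.2
  da[spurious] <- sample(c("up", "down"), sum(spurious), replace = TRUE)
  mk_tab <- function(dir) data.frame(
    gene = genes, log2fc = ifelse(dir == "up", 2, -2), p = 0.001,
    padj = 0.001, direction = ifelse(dir == "ns", "up", dir),
    deg = dir != "ns", stringsAsFactors = FALSE)

  # a crisp fuzzifier: with only 3 conditions the empirical estimate is
  # large and memberships diffuse below the 0.5 assignment threshold
  fit <- fuzzy_cmeans(x, centers = 9, m = 1.25, seed = 12)
  pat <- classify_patterns(fit, mk_tab(da), mk_tab(dd))
  planted <- truth != "none"
  expect_gte(mean(pat$pattern[planted] == truth[planted]), 0.85)
  expect_lte(mean(pat$pattern[!planted] != "none"), 0.05)
})
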