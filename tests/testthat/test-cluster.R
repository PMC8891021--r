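test_that("SOM training handles degenerate data and honors the grid", {
  x <- matrix(1, 500, 2, dimnames = list(NULL, c("a", "b")))
  m <- train_som(x, grid = c(2, 2), epochs = 5, seed = 1)
  expect_equal(as.numeric(m$codebook), rep(1, 8), tolerance = 1e-6)
  expect_equal(length(unique(m$mapping)), 1L) # all cells in one occupied node

  m10 <- train_som(
    matrix(rnorm(600), 100, 6, dimnames = list(NULL, paste0("m", 1:6))),
    grid = c(10, 10), epochs = 2, seed = 1
  )
  expect_equal(nrow(m10$codebook), 100L) # reference granularity
})

test_that("SOM recovers well-separated clusters and is deterministic", {
  set.seed(3)
  x <- matrix(rnorm(4000 * 2, sd = 0.5), ncol = 2, dimnames = list(NULL, c("a", "b")))
  x[1:2000, 1] <- x[1:2000, 1] + 10
  m <- train_som(x, grid = c(2, 1), epochs = 10, seed = 5)
  truth <- rep(1:2, each = 2000)
  agree <- max(mean((m$mapping == 1) == (truth == 1)), mean((m$mapping == 2) == (truth == 1)))
  expect_gte(agree, 0.99)
  # quantization error is monitored per epoch: it settles at the
  # within-cluster noise scale and never deteriorates materially
  expect_lt(m$qe[length(m$qe)], 0.7)
  expect_lte(max(diff(m$qe)), 0.02)
  # determinism
  m2 <- train_som(x, grid = c(2, 1), epochs = 10, seed = 5)
  expect_identical(m$codebook, m2$codebook)
  expect_identical(m$mapping, m2$mapping)
  # predict maps training data to the stored units
  expect_equal(predict(m, x), m$mapping)
})

test_that("state markers are rejected from clustering input", {
  panel <- data.frame(
    marker = c("t1", "s1"), class = c("type", "state"), cofactor = 5
  )
  x <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("t1", "s1")))
  expect_error(
    train_som(x, type_markers = c("t1", "s1"), grid = c(2, 2), panel = panel),
    "state markers"
  )
  expect_silent(invisible(train_som(x, type_markers = "t1", grid = c(2, 2), panel = panel, epochs = 2)))
})

test_that("consensus metaclustering finds the planted number of blobs", {
  make_blobs <- function(seed) {
    set.seed(seed)
    centers <- matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE)
    cb <- centers[rep(1:3, each = 8), ] + matrix(rnorm(48, sd = 0.3), 24, 2)
    rownames(cb) <- paste0("n", 1:24)
    cb
  }
  hits <- vapply(1:100, function(s) {
    mt <- consensus_metacluster(make_blobs(s), k_range = 2:6, n_subsamples = 30, seed = s)
    mt$chosen_k == 3L
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # perfectly separated blobs: consensus entries are exactly 0 or 1, and the
  # labels recover the blobs
  cb <- make_blobs(1)
  mt <- consensus_metacluster(cb, k_range = 2:6, n_subsamples = 50, seed = 2)
  cm <- mt$consensus[["3"]]
  expect_true(all(cm %in% c(0, 1)))
  expect_equal(length(unique(mt$labels[1:8])), 1L)

  # duplicated codebook rows always share a metacluster
  cb2 <- rbind(cb, cb[1, , drop = FALSE])
  rownames(cb2)[25] <- "dup"
  mt2 <- consensus_metacluster(cb2, k_range = 2:6, n_subsamples = 50, seed = 3)
  expect_equal(unname(mt2$labels["dup"]), unname(mt2$labels["n1"]))
  expect_error(consensus_metacluster(cb, k_range = integer()), "nonempty")
})

test_that("metacluster annotation merges and relabels nodes", {
  set.seed(4)
  cb <- matrix(rnorm(40), 20, 2, dimnames = list(paste0("n", 1:20), c("a", "b")))
  cb[11:20, ] <- cb[11:20, ] + 10
  mt <- consensus_metacluster(cb, k_range = 2:4, n_subsamples = 20, seed = 1)
  map <- setNames(
    rep("all_cells", mt$chosen_k),
    as.character(seq_len(mt$chosen_k))
  )
  ann <- annotate_metaclusters(mt, map)
  expect_true(all(ann$annotated_labels == "all_cells"))
  expect_error(annotate_metaclusters(mt, c(`99` = "x")), "unknown")
})

test_that("cluster summaries match hand computation and sum to one", {
  ev <- data.frame(
    sample_id = c("s1", "s1", "s1", "s1", "s2"),
    m1 = c(1, 2, 3, 10, 5), m2 = c(0, 0, 1, 1, 0.5)
  )
  labels <- c("A", "A", "A", "B", "A")
  ft <- summarize_clusters(ev, labels, markers = c("m1", "m2"), min_cells = 1L)
  s1a <- ft[ft$sample_id == "s1" & ft$cluster_id == "A", ]
  expect_equal(s1a$n_cells, 3L)
  expect_equal(s1a$freq, 0.75)
  expect_equal(s1a$m1, 2) # median(1, 2, 3)
  expect_equal(s1a$m2, 0)
  # empty combination emitted with count 0 and missing medians
  s2b <- ft[ft$sample_id == "s2" & ft$cluster_id == "B", ]
  expect_equal(s2b$n_cells, 0L)
  expect_true(is.na(s2b$m1))
  # frequencies sum to 1 per sample
  sums <- tapply(ft$freq, ft$sample_id, sum)
  expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-9)
  # low-abundance rule: medians suppressed below min_cells
  ft10 <- summarize_clusters(ev, labels, markers = "m1", min_cells = 4L)
  expect_true(all(is.na(ft10$m1)))
  expect_error(summarize_clusters(ev, labels[-1]), "one label per cell")
})

test_that("iterative subclustering preserves the partition property", {
  set.seed(8)
  x <- matrix(rnorm(3000 * 2, sd = 0.4), ncol = 2, dimnames = list(NULL, c("a", "b")))
  x[1:1500, 1] <- x[1:1500, 1] + 8
  x[1:750, 2] <- x[1:750, 2] + 8
  m <- train_som(x, grid = c(2, 1), epochs = 6, seed = 1)
  # restrict to one main population and re-cluster
  main <- which(m$mapping == m$mapping[1])
  m_sub <- train_som(x[main, , drop = FALSE], grid = c(2, 1), epochs = 6, seed = 2)
  expect_equal(length(m_sub$mapping), length(main))
  # composing labels still partitions all cells exactly once
  labels <- as.character(m$mapping)
  labels[main] <- paste0(labels[main], ".", m_sub$mapping)
  expect_equal(length(labels), nrow(x))
  expect_false(anyNA(labels))
})
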