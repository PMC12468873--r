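test_that("mutual information between channels matches the joint-count oracle", {
  set.seed(6)
  x <- rbind(sample(2, 60, TRUE), sample(3, 60, TRUE), rep(1L, 60))
  x[2, ] <- ifelse(x[1, ] == 1, x[2, ], 3L)   # induce dependence
  om <- mutual_info_matrix(x, sizes = c(2L, 3L, 2L))
  ## oracle by explicit contingency table
  tab <- table(x[1, ], x[2, ]) / 60
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  oracle <- H(rowSums(tab)) + H(colSums(tab)) - H(as.vector(tab))
  expect_equal(om[1, 2], oracle, tolerance = 1e-12)
  ## a constant channel has a zero row and column
  expect_equal(om[3, ], rep(0, 3))
  expect_equal(om[, 3], rep(0, 3))
  ## two identical balanced binary channels share log 2 nats
  y <- rbind(rep(1:2, 30), rep(1:2, 30))
  omy <- mutual_info_matrix(y, sizes = c(2L, 2L))
  expect_equal(omy[1, 2], log(2), tolerance = 1e-12)
})

test_that("spectral partitioning recovers blocks and respects the size cap", {
  ## two decoupled blocks are recovered exactly
  om <- matrix(0, 6, 6)
  om[1:3, 1:3] <- 0.5; om[4:6, 4:6] <- 0.4
  diag(om) <- 1
  gs <- spectral_partition(om, max_size = 32L)
  gs <- lapply(gs, sort)
  expect_true(list(1:3) %in% gs || any(vapply(gs, identical, NA, 1:3)))
  expect_true(any(vapply(gs, identical, NA, 4:6)))
  ## 40 mutually dependent channels: the cap binds at exactly 32
  om2 <- matrix(0.5, 40, 40); diag(om2) <- 1
  gs2 <- spectral_partition(om2, max_size = 32L)
  expect_identical(length(gs2[[1]]), 32L)
  ## planted blocks with noise
  set.seed(8)
  om3 <- matrix(abs(rnorm(100, 0, 0.01)), 10, 10)
  om3 <- (om3 + t(om3)) / 2
  om3[1:5, 1:5] <- om3[1:5, 1:5] + 1
  om3[6:10, 6:10] <- om3[6:10, 6:10] + 0.8
  diag(om3) <- 2
  gs3 <- lapply(spectral_partition(om3, 32L), sort)
  expect_true(any(vapply(gs3, identical, NA, 1:5)))
  expect_true(any(vapply(gs3, identical, NA, 6:10)))
})

test_that("group compression is a lossless map to unique states", {
  ## constant group: a single state, flagged static
  cg <- compress_group(matrix(2L, 2, 10))
  expect_true(cg$static)
  expect_identical(max(cg$states), 1L)
  ## three distinct patterns with occurrences 5/3/2
  pats <- cbind(c(1L, 1L), c(2L, 1L), c(1L, 2L))
  obs <- pats[, c(rep(1, 5), rep(2, 3), rep(3, 2))]
  cg2 <- compress_group(obs, sizes = c(2L, 2L))
  expect_equal(sort(colSums(cg2$a) / 2), c(2, 3, 5))
  ## argmax reconstruction of every frame from its state is exact
  for (t in seq_len(ncol(obs)))
    expect_identical(cg2$patterns[[cg2$states[t]]], obs[, t])
})

test_that("transition accumulation assigns one slot per unique successor", {
  b <- accumulate_transitions(c(1L, 2L, 1L, 2L, 1L))
  expect_identical(dim(b)[3], 1L)
  expect_equal(b[2, 1, 1], 2)
  expect_equal(b[1, 2, 1], 2)
  b2 <- accumulate_transitions(c(1L, 2L, 1L, 3L, 1L, 2L))
  expect_identical(dim(b2)[3], 2L)
  expect_equal(b2[2, 1, 1], 2)  # first-discovered successor sits in slot 1
  expect_equal(b2[3, 1, 2], 1)
  ## random sequences: every bigram lands in exactly one slot, and slot
  ## counts reproduce bigram counts
  set.seed(10)
  for (i in 1:10) {
    s <- sample(5L, 60, TRUE)
    b3 <- accumulate_transitions(s, n_states = 5L)
    big <- table(paste(s[-60], s[-1]))
    for (nm in names(big)) {
      ft <- as.integer(strsplit(nm, " ")[[1]])
      expect_equal(sum(b3[ft[2], ft[1], ]), unname(big[nm]))
      expect_identical(sum(b3[ft[2], ft[1], ] > 0), 1L)
    }
    ## path dimension equals the maximum out-degree
    odeg <- max(rowSums(table(s[-60], s[-1]) > 0))
    expect_identical(dim(b3)[3], as.integer(odeg))
  }
})

test_that("two independent alternating channels factorise into two factors", {
  Tn <- 64L
  ch1 <- rep(c(1L, 2L), Tn / 2)
  ch2 <- rep(c(1L, 1L, 2L, 2L), Tn / 4)
  obs <- rbind(ch1, ch2)
  lay <- list(n_channels = 2L, sizes = c(2L, 2L),
              streams = c("pixel", "pixel"))
  cfg <- denovo_config()
  m <- learn_structure(obs, cfg, layout = lay)
  expect_identical(length(m$factors), 2L)
  expect_identical(n_levels(m), 2L)
  for (f in m$factors) expect_identical(length(f$keys), 2L)
  ## replay is exact
  expect_true(replay_epochs(m, obs)$exact)
})

test_that("game structure learning yields a 2-level stream-separated model", {
  p <- fixture_pipeline()
  m <- p$m1
  expect_identical(n_levels(m), 2L)
  ## every non-static channel has exactly one parent factor
  chans <- sort(unlist(lapply(m$factors, function(f) f$channels)))
  expect_identical(chans, setdiff(seq_len(111L), m$static))
  ## streams are kept separate below the final level
  for (f in m$factors)
    expect_identical(length(unique(m$layout$streams[f$channels])), 1L)
  ## group sizes never exceed the bound
  expect_true(all(vapply(m$factors, function(f) length(f$channels), 1L) <=
                    m$config$max_group))
  ## lossless compression of the training stream
  expect_true(replay_epochs(m, p$frames$obs[, 1:2000])$exact)
})

test_that("emptied skeletons keep the grouping but no counts", {
  p <- fixture_pipeline()
  sk <- empty_counts(p$m1)
  expect_identical(sk$phase, "skeleton")
  expect_identical(lapply(sk$factors, function(f) f$channels),
                   lapply(p$m1$factors, function(f) f$channels))
  expect_identical(sum(vapply(sk$factors, function(f) length(f$keys), 1L)), 0L)
  expect_identical(sk$top$n_states, 0L)
})
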