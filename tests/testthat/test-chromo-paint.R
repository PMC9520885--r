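test_that("forward-backward posteriors match exhaustive path enumeration", {
  set.seed(31)
  for (i in 1:6) {
    D <- sample(2:4, 1); L <- sample(3:6, 1)
    inst <- random_hmm_instance(D, L)
    got <- copying_forward_backward(inst$target, inst$donors,
                                    inst$distances, inst$rho, inst$theta)
    want <- brute_hmm(inst$target, inst$donors, inst$distances,
                      inst$rho, inst$theta)
    expect_equal(unname(got$posterior), want$posterior, tolerance = 1e-10)
    expect_equal(got$loglik, log(want$lik), tolerance = 1e-10)
    expect_true(all(abs(rowSums(got$posterior) - 1) < 1e-9))
  }
})

test_that("posterior degenerates correctly in closed-form limits", {
  set.seed(32)
  donors <- matrix(rbinom(4 * 6, 1, 0.5), 4, 6)
  target <- donors[2, ]
  d <- rep(0.01, 5)

  # near-uninformative emission: posterior ~ 1/D everywhere
  p <- copying_forward_backward(target, donors, d, rho = 1, theta = 0.4999)
  expect_true(all(abs(p$posterior - 0.25) < 1e-3))

  # single site: posterior proportional to the emission likelihood
  th <- 0.1
  p1 <- copying_forward_backward(target[1], donors[, 1, drop = FALSE],
                                 numeric(0), rho = 1, theta = th)
  match1 <- donors[, 1] == target[1]
  want <- ifelse(match1, 1 - th, th)
  expect_equal(unname(p1$posterior[1, ]), want / sum(want),
               tolerance = 1e-12)

  # input validation
  expect_error(copying_forward_backward(target[1:3], donors, d, 1, 0.1),
               "site grids")
  expect_error(copying_forward_backward(target, donors, d, 0, 0.1), "rho")
  expect_error(copying_forward_backward(target, donors, d, 1, 0.6), "theta")
})

test_that("Viterbi attains the exhaustive maximum path probability", {
  set.seed(33)
  for (i in 1:6) {
    D <- sample(2:3, 1); L <- sample(3:6, 1)
    inst <- random_hmm_instance(D, L)
    got <- viterbi_copying(inst$target, inst$donors, inst$distances,
                           inst$rho, inst$theta)
    want <- brute_hmm(inst$target, inst$donors, inst$distances,
                      inst$rho, inst$theta)
    # the returned path achieves the global maximum probability
    got_prob <- path_prob(got$path, inst$target, inst$donors,
                          inst$distances, inst$rho, inst$theta)
    expect_equal(log(got_prob), log(want$max_path_prob), tolerance = 1e-10)
  }

  # exact-copy target with small theta: constant path on that donor
  donors <- matrix(rbinom(3 * 8, 1, 0.5), 3, 8)
  donors[2, ] <- 1 - donors[1, ]
  donors[3, 1:4] <- 1 - donors[1, 1:4]
  v <- viterbi_copying(donors[1, ], donors, rep(0.01, 7), rho = 1,
                       theta = 0.01)
  expect_equal(v$path, rep(1L, 8))

  # no-switch limit: constant path at the best single donor
  set.seed(34)
  inst <- random_hmm_instance(3, 6)
  v0 <- viterbi_copying(inst$target, inst$donors, inst$distances,
                        rho = 1e-12, theta = 0.2)
  expect_equal(length(unique(v0$path)), 1L)
  marg <- sapply(1:3, function(d)
    prod(ifelse(inst$donors[d, ] == inst$target, 0.8, 0.2)))
  expect_equal(unique(v0$path), which.max(marg))
})

test_that("label collapse sums donor posteriors and breaks ties lexicographically", {
  # engineered painting object
  post <- rbind(c(0.3, 0.3, 0.4),
                c(0.2, 0.2, 0.6),
                c(0.5, 0.1, 0.4))
  colnames(post) <- paste0("donor", 1:3)
  ptg <- structure(list(posterior = post, loglik = 0,
                        log_scale = numeric(3),
                        donor_ids = colnames(post)), class = "painting")
  lp <- label_sites_by_tag_haplotype(ptg, c("A", "A", "B"))
  expect_equal(unname(lp$label_posterior[, "A"]), c(0.6, 0.4, 0.6))
  expect_equal(lp$labels, c("A", "B", "A"))
  expect_true(all(abs(rowSums(lp$label_posterior) - 1) < 1e-12))

  # exact tie 0.5/0.5: lexicographically smaller label wins
  post2 <- matrix(c(0.5, 0.5), 1, 2,
                  dimnames = list(NULL, c("d1", "d2")))
  ptg2 <- structure(list(posterior = post2, loglik = 0,
                         log_scale = 0, donor_ids = c("d1", "d2")),
                    class = "painting")
  expect_equal(label_sites_by_tag_haplotype(ptg2, c("B", "A"))$labels, "A")

  # all donors one label
  lp3 <- label_sites_by_tag_haplotype(ptg, c("X", "X", "X"))
  expect_true(all(lp3$labels == "X"))
  expect_true(all(abs(lp3$label_posterior - 1) < 1e-12))

  expect_error(label_sites_by_tag_haplotype(ptg, c("A", NA, "B")),
               "unlabeled")

  # random painting: grouped sums equal independent recomputation
  set.seed(35)
  inst <- random_hmm_instance(4, 5)
  ptg4 <- copying_forward_backward(inst$target, inst$donors,
                                   inst$distances, inst$rho, inst$theta)
  labs <- c("A", "B", "A", "B")
  lp4 <- label_sites_by_tag_haplotype(ptg4, labs)
  expect_equal(unname(lp4$label_posterior[, "A"]),
               unname(ptg4$posterior[, 1] + ptg4$posterior[, 3]))
})

test_that("switch points sit exactly where consecutive labels differ", {
  expect_equal(nrow(detect_switch_points(rep("A", 5))), 0L)
  sw <- detect_switch_points(c("A", "A", "B", "B"), positions = c(10, 20, 30, 40))
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$left_site, 2L)
  expect_equal(sw$right_site, 3L)
  expect_equal(sw$left_pos, 20)
  expect_equal(sw$from, "A")
  expect_equal(sw$to, "B")
  expect_error(detect_switch_points(character(0)), "empty")
})

test_that("homozygote selection matches truth on panels and genotype tables", {
  set.seed(36)
  panel <- simulate_group_panel(c("00000", "11100"), n_homozygotes = 5,
                                n_sites = 40, seed = 36)
  ids <- select_homozygotes(panel, "11100")
  expect_setequal(ids, unique(panel$sample_id)[6:10])

  g <- rbind(a = c(0, 0, 0, 0, 0), b = c(2, 2, 2, 0, 0),
             c = c(1, 2, 2, 0, 0))
  expect_equal(select_homozygotes(g, "11100"), "b")
  expect_equal(select_homozygotes(g, "00000"), "a")
})

test_that("painting quality summarises the stored posterior maxima", {
  set.seed(37)
  donors <- matrix(rbinom(4 * 10, 1, 0.5), 4, 10)
  d <- rep(0.01, 9)
  # near-uninformative: median max posterior ~ 1/D
  pu <- copying_forward_backward(donors[1, ], donors[2:4, ], d[1:9],
                                 rho = 1, theta = 0.4999)
  expect_equal(painting_quality(pu)$median, 1 / 3, tolerance = 1e-3)
  # exact copy with a distinct donor set: median near 1
  donors2 <- rbind(donors[1, ], 1 - donors[1, ], rev(donors[1, ]))
  pc <- copying_forward_backward(donors[1, ], donors2, d[1:9],
                                 rho = 0.1, theta = 0.01)
  expect_gt(painting_quality(pc)$median, 0.95)
  # equals independent recomputation
  q <- painting_quality(list(pu, pc))
  expect_equal(q$per_chromosome[1], median(apply(pu$posterior, 1, max)))
  expect_equal(q$per_chromosome[2], median(apply(pc$posterior, 1, max)))
  expect_error(painting_quality(list()), "at least one")
})

test_that("matching-donor posterior is monotone as theta decreases", {
  set.seed(38)
  donors <- matrix(rbinom(5 * 12, 1, 0.5), 5, 12)
  target <- donors[1, ]
  d <- runif(11, 0.001, 0.02)
  thetas <- c(0.4, 0.2, 0.1, 0.02)
  posts <- sapply(thetas, function(th)
    copying_forward_backward(target, donors, d, rho = 2,
                             theta = th)$posterior[, 1])
  for (j in 2:length(thetas)) {
    expect_true(all(posts[, j] >= posts[, j - 1] - 1e-12))
  }
})

test_that("painting recovers simulated mosaics at donor-label level", {
  set.seed(39)
  # well-separated founders: complementary blocks
  founders <- matrix(rbinom(4 * 150, 1, 0.5), 4, 150)
  d <- rep(2e-4, 149)
  sim <- simulate_mosaic_panel(founders, d, 25, switch_scale = 60,
                               mutation_rate = 0.001, seed = 40)
  acc <- numeric(25)
  for (i in 1:25) {
    pt <- copying_forward_backward(sim$panel$alleles[i, ], founders, d,
                                   rho = 60, theta = 0.01)
    path <- max.col(pt$posterior, ties.method = "first")
    acc[i] <- mean(path == sim$truth$paths[i, ])
  }
  expect_gte(mean(acc), 0.95)

  # switch localisation: with complementary founders (informative at
  # every site) detected switches sit within one inter-site interval of
  # the true switch for >= 95% of true switches
  f2 <- rbind(rbinom(150, 1, 0.5))
  f2 <- rbind(f2, 1 - f2)
  sim2 <- simulate_mosaic_panel(f2, d, 60, switch_scale = 25,
                                mutation_rate = 0, seed = 42)
  hits <- 0; total <- 0
  for (i in 1:60) {
    pt <- copying_forward_backward(sim2$panel$alleles[i, ], f2, d,
                                   rho = 25, theta = 0.01)
    path <- max.col(pt$posterior, ties.method = "first")
    true_sw <- which(diff(sim2$truth$paths[i, ]) != 0)
    got_sw <- which(diff(path) != 0)
    total <- total + length(true_sw)
    hits <- hits + sum(vapply(true_sw, function(s)
      any(abs(got_sw - s) <= 1), logical(1)))
  }
  expect_gte(hits / total, 0.95)
})

test_that("panel painting is leave-one-out and labels are tag haplotypes", {
  set.seed(41)
  panel <- simulate_group_panel(c("00000", "11111"), n_homozygotes = 4,
                                n_sites = 30, noise = 0.01, seed = 41)
  pp <- paint_panel(panel)
  expect_equal(dim(pp$labels_matrix), c(16L, 30L))
  lab <- tag_labels(panel)
  # at the tag sites the called label should match each chromosome's own
  acc <- mean(pp$labels_matrix[, panel$tag_sites[3]] == lab)
  expect_gt(acc, 0.9)
})
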