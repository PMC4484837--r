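test_that("sensitivity and specificity are control-panel percentages", {
  pos <- paste0("p", 1:44); neg <- paste0("n", 1:44)
  expect_equal(sensitivity_specificity(pos, pos, neg),
               c(sensitivity = 100, specificity = 100))
  expect_equal(unname(sensitivity_specificity(pos[1:5], pos, neg)["sensitivity"]),
               100 * 5 / 44)
  expect_equal(round(100 * 5 / 44, 1), 11.4)
  hit <- c(pos[1:10], neg[1:11], "other_gene")
  ss <- sensitivity_specificity(hit, pos, neg)
  expect_equal(unname(ss), c(100 * 10 / 44, 100 * 33 / 44))
  # invariance to genes outside the panel
  ss2 <- sensitivity_specificity(c(hit, paste0("x", 1:500)), pos, neg)
  expect_equal(ss, ss2)
  expect_error(sensitivity_specificity(hit, character(0), neg), "non-empty")
  expect_error(sensitivity_specificity(hit, pos, pos[1]), "overlap")
})

test_that("informative-gene counts floor 75% of the sample size", {
  de <- structure(data.frame(gene_id = paste0("g", 1:100),
                             adj_p_value = seq(0.001, 1, length.out = 100)),
                  class = c("de_result", "data.frame"))
  expect_length(select_informative_genes(de, 41), 30L)
  expect_length(select_informative_genes(de, 16), 12L)
  expect_length(select_informative_genes(de, 27), 20L)
  top <- select_informative_genes(de, 16)
  expect_equal(top, paste0("g", 1:12))       # best adjusted p first
  expect_warning(all_g <- select_informative_genes(de, 200), "returning all")
  expect_length(all_g, 100L)
})

test_that("common-DEG percentages follow the pairwise-share formula", {
  a <- paste0("g", 1:10); b <- paste0("g", 6:25)
  cd <- common_deg_matrix(list(A = a, B = b))
  expect_equal(cd$D_pair["A", "B"], 5L)
  expect_equal(cd$P["A", "B"], 50)            # 5/10
  expect_equal(cd$P["B", "A"], 25)            # 5/20
  expect_equal(cd$P_avg["A", "B"], 37.5)
  expect_equal(cd$P_avg, t(cd$P_avg))

  same <- common_deg_matrix(list(X = a, Y = a, Z = a))
  expect_true(all(same$P_avg[upper.tri(same$P_avg)] == 100))
  disj <- common_deg_matrix(list(X = a, Y = paste0("h", 1:4)))
  expect_equal(disj$P_avg["X", "Y"], 0)
  expect_warning(common_deg_matrix(list(X = a, Y = a, E = character(0))),
                 "excluded")
})

test_that("intersect_all equals brute-force set intersection", {
  set.seed(6)
  lists <- lapply(1:4, function(i) sample(paste0("g", 1:60), 30))
  names(lists) <- letters[1:4]
  brute <- Filter(function(g) all(vapply(lists, function(l) g %in% l, logical(1))),
                  paste0("g", 1:60))
  expect_setequal(intersect_all(lists), brute)
  expect_equal(intersect_all(list(a = lists[[1]], b = lists[[1]])), lists[[1]])
  expect_length(intersect_all(list(a = lists[[1]], b = character(0))), 0L)
})

test_that("rank dendrogram clusters methods by common-DEG rank distance", {
  mk_de <- function(p) {
    structure(data.frame(gene_id = paste0("g", seq_along(p)),
                         adj_p_value = p,
                         stringsAsFactors = FALSE),
              class = c("de_result", "data.frame"))
  }
  # three common DEGs; methods 1 and 2 rank them identically, 3 reverses
  p1 <- c(0.001, 0.002, 0.003, 0.9)
  p3 <- c(0.003, 0.002, 0.001, 0.9)
  dres <- list(m1 = mk_de(p1), m2 = mk_de(p1), m3 = mk_de(p3))
  dd <- method_rank_dendrogram(dres, alpha = 0.05)
  expect_setequal(dd$common_genes, paste0("g", 1:3))
  dm <- as.matrix(dd$dist)
  expect_equal(dm["m1", "m2"], 0)
  expect_equal(dm["m1", "m3"], sqrt(8))      # ranks (1,2,3) vs (3,2,1)
  expect_equal(dd$hclust$merge[1, ], c(-1, -2))  # identical pair merges first
  expect_length(dd$hclust$order, 3L)
  expect_error(method_rank_dendrogram(list(m1 = mk_de(rep(0.9, 3)),
                                           m2 = mk_de(rep(0.9, 3)))),
               "loosen alpha")
})

test_that("rank aggregation averages criterion ranks into a final rank", {
  # printed criterion ranks for one method average to 26.5/6
  expect_equal(mean(c(5, 5, 5, 1.5, 5, 5)), 26.5 / 6)
  crit <- list(bias = c(A = 0.2, B = 0.4, C = 0.3),
               sensitivity = c(A = 90, B = 50, C = 70),
               prediction_error = c(A = 1, B = 8, C = 4))
  rs <- summarize_ranks(crit)
  expect_equal(unname(rs$final_rank), c(1, 2, 3))
  expect_equal(names(rs$final_rank), c("A", "C", "B"))
  expect_equal(rs$recommended, "A")
  # permuting criterion order changes nothing
  rs2 <- summarize_ranks(crit[c(3, 1, 2)])
  expect_equal(rs2$final_rank, rs$final_rank)
  # incomplete criteria are dropped with a warning
  crit$common_degs <- c(A = 10, B = 20)
  expect_warning(rs3 <- summarize_ranks(crit), "dropped")
  expect_equal(rs3$final_rank, rs$final_rank)
})

test_that("LOOCV separates separable groups and fails on shuffled labels", {
  set.seed(71)
  n <- 20
  labels <- rep(c("A", "B"), each = n / 2)
  feats <- matrix(rnorm(n * 15), n, 15)
  feats[labels == "B", ] <- feats[labels == "B", ] + 10   # 10 SD shift
  res <- loocv_errors(feats, labels, seed = 71)
  expect_equal(res$n_runs, n)
  expect_named(res$per_classifier,
               c("naive_bayes", "neural_network", "knn", "svm", "random_forest"))
  expect_equal(res$mean, 0)

  set.seed(72)
  shuffled <- sample(labels)
  feats0 <- matrix(rnorm(n * 15), n, 15)
  res0 <- loocv_errors(feats0, shuffled, seed = 72)
  expect_gte(res0$mean, 35); expect_lte(res0$mean, 65)
  expect_true(res0$ci[1] <= res0$mean && res0$mean <= res0$ci[2])
})
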