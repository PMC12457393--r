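clause <- function(dim, score, text = c("green space", "planning")) {
  list(text = text, dimension = dim, score = score)
}
doc <- function(clauses, id = "d1") list(doc_id = id, level = "municipal",
                                         year = 2020, clauses = clauses)

test_that("PSI matches hand evaluations of the weighted rubric", {
  all5 <- doc(list(clause("mandatoriness", 5), clause("penalty", 5),
                   clause("participation", 5)))
  r <- score_psi(list(all5))
  expect_equal(r$psi_raw, 5)
  expect_equal(r$psi_scaled, 100)

  d543 <- doc(list(clause("mandatoriness", 5), clause("penalty", 4),
                   clause("participation", 3)))
  r2 <- score_psi(list(d543))
  expect_equal(r2$psi_raw, 4.1)                 # 0.4*5 + 0.3*4 + 0.3*3
  expect_equal(r2$psi_scaled, 82)
  expect_equal(unname(r2$weights), c(0.40, 0.30, 0.30))
})

test_that("PSI is monotone in clause scores and invariant to document partition", {
  base <- list(clause("mandatoriness", 3), clause("mandatoriness", 4),
               clause("penalty", 2), clause("participation", 5))
  r1 <- score_psi(list(doc(base)))
  raised <- base
  raised[[3]]$score <- 4
  expect_gt(score_psi(list(doc(raised)))$psi_raw, r1$psi_raw)
  split2 <- list(doc(base[1:2], "a"), doc(base[3:4], "b"))
  expect_equal(score_psi(split2)$psi_raw, r1$psi_raw)
})

test_that("PSI errors identify missing dimensions and bad scores", {
  expect_error(score_psi(list(doc(list(clause("penalty", 3))))),
               "mandatoriness")
  expect_error(score_psi(list(doc(list(clause("penalty", 6))))), "1, 5")
  expect_error(score_psi(list(doc(list(clause("unknown", 3))))), "unknown")
})

test_that("network metrics match hand counts on canonical graphs", {
  terms <- c("a", "b", "c", "d")
  # complete graph: every pair co-occurs in >= 2 clauses
  complete <- doc(lapply(1:3, function(i) clause("penalty", 3, text = terms)))
  filler <- doc(list(clause("mandatoriness", 3, text = "a"),
                     clause("participation", 3, text = "a")))
  net <- build_cooccurrence(list(complete, filler), terms, min_cooccur = 2)
  expect_equal(net$density, 1)
  expect_equal(net$clustering, 1)
  expect_equal(net$pci, 100)

  # star on 4 nodes: hub-leaf pairs twice each, leaves never together
  star_clauses <- unlist(lapply(c("b", "c", "d"), function(leaf) {
    lapply(1:2, function(i) clause("penalty", 3, text = c("a", leaf)))
  }), recursive = FALSE)
  star <- list(doc(star_clauses), filler)
  net2 <- build_cooccurrence(star, terms, min_cooccur = 2)
  expect_equal(net2$density, 0.5)               # 3 edges of 6 possible
  expect_equal(net2$clustering, 0)
  expect_equal(net2$pci, 30)
  expect_equal(net2$top_centrality_term, "a")
})

test_that("clustering matches the naive triangle-count oracle on random graphs", {
  for (case in 1:10) {
    withr::with_seed(case, {
      k <- sample(4:8, 1)
      adj <- matrix(rbinom(k * k, 1, 0.45), k)
      adj <- (adj | t(adj)) * 1; diag(adj) <- 0
    })
    gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    loc <- igraph::transitivity(gr, type = "local", isolates = "zero")
    loc[igraph::degree(gr) < 2] <- 0
    expect_equal(mean(loc), clustering_naive(adj), tolerance = 1e-12)
  }
})

test_that("PCI follows its formula and is strictly increasing in both inputs", {
  expect_equal(pci_index(0.38, 0.42), 39.6)     # noted mismatch with published PCI
  expect_gt(pci_index(0.39, 0.42), pci_index(0.38, 0.42))
  expect_gt(pci_index(0.38, 0.43), pci_index(0.38, 0.42))
  expect_error(pci_index(1.2, 0.5), "density")
})

test_that("degenerate corpora are rejected", {
  d <- doc(list(clause("mandatoriness", 3, text = "zz"),
                clause("penalty", 3, text = "zz"),
                clause("participation", 3, text = "zz")))
  expect_error(build_cooccurrence(list(d), c("a", "b")), "degenerate network")
})

test_that("generated corpora carry their expected PSI and are deterministic", {
  docs1 <- gen_policy_corpus("strong", seed = 5)
  docs2 <- gen_policy_corpus("strong", seed = 5)
  expect_identical(docs1, docs2)
  truth <- attr(docs1, "truth")
  r <- score_psi(docs1)
  # clause scores are draws from the profile distribution: sample mean near
  # expectation (72 clauses, per-dimension sd < 1)
  expect_lt(abs(r$psi_raw - truth$expected_psi_raw), 0.5)

  fixed <- gen_policy_corpus(list(mandatoriness = 5, penalty = 4, participation = 3),
                             seed = 1)
  expect_equal(score_psi(fixed)$psi_raw, 4.1)   # degenerate distributions are exact
  expect_equal(attr(fixed, "truth")$expected_psi_scaled, 82)

  expect_error(gen_policy_corpus("mighty"), "profile")

  # stronger profiles knit denser, more clustered networks
  lex <- gen_policy_corpus("weak", seed = 3)
  nw <- build_cooccurrence(lex, greengov:::default_lexicon())
  ns <- build_cooccurrence(gen_policy_corpus("strong", seed = 3),
                           greengov:::default_lexicon())
  expect_gt(ns$density, nw$density)
  expect_gt(ns$pci, nw$pci)
})

test_that("policy corpus JSON round-trips", {
  docs <- gen_policy_corpus("medium", seed = 2, n_docs = 2, clauses_per_dim = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_policy_corpus(docs, path)
  back <- read_policy_corpus(path)
  expect_equal(score_psi(back)$psi_raw, score_psi(docs)$psi_raw)
  expect_equal(back[[1]]$clauses[[1]]$text, docs[[1]]$clauses[[1]]$text)
})
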