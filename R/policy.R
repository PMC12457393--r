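# Policy corpora are lists of documents; each document is a list with
# doc_id, level, year and clauses, where a clause is
# list(text = character tokens, dimension = one of the three scoring
# dimensions, score = integer 1..5).

psi_dimensions <- c("mandatoriness", "penalty", "participation")
psi_weights <- c(mandatoriness = 0.40, penalty = 0.30, participation = 0.30)

check_corpus <- function(docs) {
  if (!length(docs)) stop("empty policy corpus", call. = FALSE)
  for (d in docs) {
    for (cl in d$clauses) {
      if (!cl$dimension %in% psi_dimensions) {
        stop(sprintf("unknown clause dimension '%s'", cl$dimension), call. = FALSE)
      }
      s <- cl$score
      if (!is_count(s) || s < 1 || s > 5) {
        stop("clause scores must be integers in [1, 5]", call. = FALSE)
      }
    }
  }
  invisible(docs)
}

#' Policy Strength Index (PSI)
#'
#' Scores a corpus of clause-coded legal documents on three dimensions —
#' clause mandatoriness, penalty severity, and public participation — each
#' coded 1 to 5 per clause. Dimension scores are clause means, and
#' \deqn{PSI = \sum_d \mathrm{score}_d \times \mathrm{weight}_d}
#' with weights (0.40, 0.30, 0.30). The raw index lies in `[1, 5]`; the
#' conventional 0-100 presentation is `20 x` the raw index and is reported
#' alongside.
#'
#' @param docs a policy corpus (list of documents; see
#'   [gen_policy_corpus()] for the schema, or [read_policy_corpus()]).
#' @return Object of class `psi_result`: `dimension_scores`, `weights`,
#'   `psi_raw`, `psi_scaled`, `n_clauses`.
#' @export
score_psi <- function(docs) {
  check_corpus(docs)
  clauses <- unlist(lapply(docs, `[[`, "clauses"), recursive = FALSE)
  dims <- vapply(clauses, `[[`, character(1), "dimension")
  scores <- vapply(clauses, function(cl) as.numeric(cl$score), numeric(1))
  missing <- setdiff(psi_dimensions, unique(dims))
  if (length(missing)) {
    stop(sprintf("coverage error: no clauses for dimension(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  dscore <- vapply(psi_dimensions, function(d) mean(scores[dims == d]), numeric(1))
  psi_raw <- sum(dscore * psi_weights[psi_dimensions])
  structure(
    list(
      dimension_scores = dscore,
      weights = psi_weights,
      psi_raw = psi_raw,
      psi_scaled = 20 * psi_raw,
      n_clauses = length(clauses)
    ),
    class = "psi_result"
  )
}

#' @export
print.psi_result <- function(x, ...) {
  cat("Policy Strength Index\n")
  print(round(x$dimension_scores, 3))
  cat(sprintf("  PSI raw = %.3f (1-5 scale), scaled = %.1f (0-100)\n",
              x$psi_raw, x$psi_scaled))
  invisible(x)
}

#' Keyword co-occurrence network and Policy Coherence Index (PCI)
#'
#' Builds an undirected keyword network from clause token streams: nodes are
#' lexicon terms present in the corpus, and two terms are linked by the
#' number of clause windows in which both occur. Edges with fewer than
#' `min_cooccur` co-occurrences are dropped (binarization). The network is
#' summarized by its density `2m / (n(n-1))`, the mean local clustering
#' coefficient (nodes with degree < 2 contribute 0), and the degree-central
#' term; the composite index is
#' \deqn{PCI = 100 \times (0.6 \times \mathrm{density}
#'       + 0.4 \times \mathrm{clustering})}
#' on a 0-100 scale. Note that published three-city PCI tables are not
#' reproducible from their own printed density/clustering columns under this
#' formula; `pci` here always follows the formula.
#'
#' @param docs a policy corpus.
#' @param lexicon character vector of keyword terms to track.
#' @param window co-occurrence window in clauses (default 1: within-clause).
#' @param min_cooccur minimum co-occurrence count for an edge (default 2).
#' @return Object of class `semantic_network`: `graph` (igraph), `nodes`,
#'   `edge_counts` (weighted co-occurrence matrix), `density`, `clustering`,
#'   `top_centrality_term`, `pci`.
#' @export
build_cooccurrence <- function(docs, lexicon, window = 1, min_cooccur = 2) {
  check_corpus(docs)
  if (!length(lexicon)) config_error("lexicon", "must be nonempty")
  if (!is_count(window)) config_error("window", "must be a positive count")
  clauses <- unlist(lapply(docs, `[[`, "clauses"), recursive = FALSE)
  toks <- lapply(clauses, function(cl) unique(tolower(unlist(cl$text))))
  lex <- unique(tolower(lexicon))

  # Sliding window of `window` consecutive clauses (within the corpus order).
  n_cl <- length(toks)
  windows <- lapply(seq_len(max(n_cl - window + 1L, 1L)), function(i) {
    unique(unlist(toks[i:min(i + window - 1L, n_cl)]))
  })
  present <- lex[lex %in% unique(unlist(toks))]
  if (length(present) < 2L) {
    stop("degenerate network: fewer than 2 lexicon terms present in corpus", call. = FALSE)
  }
  k <- length(present)
  counts <- matrix(0L, k, k, dimnames = list(present, present))
  for (wtoks in windows) {
    hit <- present[present %in% wtoks]
    if (length(hit) >= 2L) {
      idx <- match(hit, present)
      counts[idx, idx] <- counts[idx, idx] + 1L
    }
  }
  diag(counts) <- 0L
  adj <- (counts >= min_cooccur) * 1L
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  m <- igraph::ecount(gr)
  density <- 2 * m / (k * (k - 1))
  loc <- igraph::transitivity(gr, type = "local", isolates = "zero")
  loc[igraph::degree(gr) < 2] <- 0
  clustering <- mean(loc)
  top <- present[which.max(igraph::degree(gr))]
  structure(
    list(
      graph = gr,
      nodes = present,
      edge_counts = counts,
      density = density,
      clustering = clustering,
      top_centrality_term = top,
      pci = pci_index(density, clustering)
    ),
    class = "semantic_network"
  )
}

#' Policy Coherence Index from network summaries
#'
#' `PCI = 100 * (0.6 * density + 0.4 * clustering)`.
#'
#' @param density network density in `[0, 1]`.
#' @param clustering mean local clustering coefficient in `[0, 1]`.
#' @return PCI on the 0-100 scale.
#' @export
pci_index <- function(density, clustering) {
  if (!is_prob(density)) config_error("density", "must lie in [0, 1]")
  if (!is_prob(clustering)) config_error("clustering", "must lie in [0, 1]")
  100 * (0.6 * density + 0.4 * clustering)
}

#' @export
print.semantic_network <- function(x, ...) {
  cat(sprintf("Keyword co-occurrence network: %d terms, density %.3f, clustering %.3f\n",
              length(x$nodes), x$density, x$clustering))
  cat(sprintf("  top degree term: %s; PCI = %.1f\n", x$top_centrality_term, x$pci))
  invisible(x)
}

#' Read / write a policy corpus as JSON
#'
#' Schema: an array of `{doc_id, level, year, clauses: [{text, dimension,
#' score}]}` objects; `text` is an array of tokens.
#'
#' @param path JSON file path.
#' @return a policy corpus list / `path` invisibly.
#' @export
read_policy_corpus <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  docs <- lapply(raw, function(d) {
    list(
      doc_id = d$doc_id, level = d$level, year = d$year,
      clauses = lapply(d$clauses, function(cl) {
        list(text = unlist(cl$text), dimension = cl$dimension, score = as.integer(cl$score))
      })
    )
  })
  check_corpus(docs)
}

#' @rdname read_policy_corpus
#' @param docs a policy corpus list.
#' @export
write_policy_corpus <- function(docs, path) {
  check_corpus(docs)
  jsonlite::write_json(docs, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
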