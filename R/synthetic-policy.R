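# Built-in policy keyword lexicon (also shipped as
# inst/extdata/policy_lexicon.txt for file-driven workflows).
default_lexicon <- function() {
  c("green space", "ecological restoration", "public participation",
    "punishment ladder", "mandatory provision", "supervision", "fine",
    "hearing", "planning", "protection", "compensation", "development")
}

profile_score_dists <- list(
  strong = list(
    mandatoriness = c(0, 0, 0, 0.4, 0.6),
    penalty       = c(0, 0, 0.1, 0.4, 0.5),
    participation = c(0, 0, 0.2, 0.4, 0.4)
  ),
  medium = list(
    mandatoriness = c(0, 0.2, 0.6, 0.2, 0),
    penalty       = c(0.1, 0.3, 0.4, 0.2, 0),
    participation = c(0.1, 0.3, 0.4, 0.2, 0)
  ),
  weak = list(
    mandatoriness = c(0.4, 0.4, 0.2, 0, 0),
    penalty       = c(0.5, 0.4, 0.1, 0, 0),
    participation = c(0.5, 0.3, 0.2, 0, 0)
  )
)

#' Generate a clause-coded synthetic policy corpus
#'
#' Emulates a corpus of legal documents coded on the three strength
#' dimensions (mandatoriness, penalty severity, public participation).
#' `profile` is either a named preset (`"strong"`, `"medium"`, `"weak"`) or
#' an explicit per-dimension specification: a list with entries
#' `mandatoriness`, `penalty`, `participation`, each a single fixed score
#' (1-5) or a length-5 probability vector over scores 1-5. Clause token
#' streams are drawn from a keyword lexicon with profile-dependent
#' coherence: strong corpora concentrate on a small core vocabulary (dense
#' co-occurrence network), weak corpora scatter across the lexicon.
#'
#' @param profile preset label or explicit score specification (see above).
#' @param seed random seed.
#' @param n_docs number of documents (default 3: national, provincial,
#'   municipal issuing levels).
#' @param clauses_per_dim coded clauses per dimension per document.
#' @param lexicon keyword vector (default [the built-in lexicon]).
#' @return list of policy documents (see [score_psi()] schema) with
#'   attribute `truth`: expected per-dimension scores, expected PSI raw and
#'   scaled, profile echo.
#' @export
gen_policy_corpus <- function(profile = "medium", seed = 1, n_docs = 3,
                              clauses_per_dim = 8, lexicon = default_lexicon()) {
  if (is.character(profile)) {
    if (!profile %in% names(profile_score_dists)) {
      config_error("profile", sprintf("unknown label '%s' (use strong/medium/weak)", profile))
    }
    label <- profile
    dists <- profile_score_dists[[profile]]
  } else if (is.list(profile)) {
    missing <- setdiff(psi_dimensions, names(profile))
    if (length(missing)) {
      config_error("profile", sprintf("missing dimension(s): %s", paste(missing, collapse = ", ")))
    }
    label <- "custom"
    dists <- lapply(profile[psi_dimensions], function(sp) {
      if (length(sp) == 1L) {
        if (!is_count(sp) || sp < 1 || sp > 5) config_error("profile", "fixed scores must be integers 1-5")
        replace(rep(0, 5), sp, 1)
      } else if (length(sp) == 5L) {
        if (any(sp < 0) || abs(sum(sp) - 1) > 1e-8) config_error("profile", "distributions must be probabilities summing to 1")
        sp
      } else config_error("profile", "each dimension needs a score or a length-5 distribution")
    })
    names(dists) <- psi_dimensions
  } else config_error("profile", "must be a label or a per-dimension list")
  if (!is_count(n_docs) || !is_count(clauses_per_dim)) {
    config_error("n_docs/clauses_per_dim", "must be positive counts")
  }

  exp_scores <- vapply(dists, function(p) sum(p * (1:5)), numeric(1))
  exp_psi <- sum(exp_scores * psi_weights[psi_dimensions])

  # Coherence model: the lexicon splits into small topic groups; every
  # clause speaks mostly within one topic, and stronger policy regimes mix
  # vocabulary across topics more, knitting the co-occurrence network
  # together (higher density and clustering).
  strength01 <- (exp_psi - 1) / 4
  p_mix <- 0.05 + 0.6 * strength01
  n_topics <- max(2L, ceiling(length(lexicon) / 3))
  topics <- split(lexicon, rep(seq_len(n_topics), length.out = length(lexicon)))

  levels <- rep(c("national", "provincial", "municipal"), length.out = n_docs)
  docs <- with_rng(seed, {
    lapply(seq_len(n_docs), function(d) {
      clauses <- list()
      for (dim in psi_dimensions) {
        for (j in seq_len(clauses_per_dim)) {
          score <- sample.int(5L, 1L, prob = dists[[dim]])
          topic <- topics[[sample.int(n_topics, 1L)]]
          n_in <- stats::rbinom(1L, 3L, 1 - p_mix)
          n_in <- min(n_in, length(topic))
          outside <- setdiff(lexicon, topic)
          n_out <- min(3L - n_in, length(outside))
          toks <- c(
            if (n_in > 0) sample(topic, n_in),
            if (n_out > 0) sample(outside, n_out),
            sprintf("filler_%d", sample.int(50L, 2L))
          )
          clauses[[length(clauses) + 1L]] <- list(text = toks, dimension = dim, score = score)
        }
      }
      list(doc_id = sprintf("doc_%02d", d), level = levels[d], year = 2009 + d,
           clauses = clauses)
    })
  })
  attr(docs, "truth") <- list(
    profile = label,
    expected_dimension_scores = exp_scores,
    expected_psi_raw = exp_psi,
    expected_psi_scaled = 20 * exp_psi
  )
  docs
}
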