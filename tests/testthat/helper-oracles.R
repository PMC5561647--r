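# Brute-force oracles kept independent of the package implementation.

# Union-find connected components of proteins over shared peptides.
# incidence: data frame with peptide_sequence, protein_accession.
oracle_components <- function(incidence) {
  accs <- sort(unique(incidence$protein_accession))
  parent <- stats::setNames(accs, accs)
  find <- function(a) {
    while (parent[[a]] != a) a <- parent[[a]]
    a
  }
  for (pep in unique(incidence$peptide_sequence)) {
    members <- incidence$protein_accession[incidence$peptide_sequence == pep]
    roots <- vapply(members, find, character(1))
    parent[roots] <- roots[1]
  }
  comps <- vapply(accs, find, character(1))
  split(accs, comps)
}

# Naive O(n^3) UPGMA; returns the cophenetic distance matrix.
oracle_upgma_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, length(clusters))
  coph <- matrix(0, n, n)
  dd <- d
  diag(dd) <- Inf
  while (sum(active) > 1L) {
    idx <- which(active)
    best <- c(NA, NA)
    bestv <- Inf
    for (i in idx) for (j in idx) {
      if (i < j && dd[i, j] < bestv) {
        bestv <- dd[i, j]
        best <- c(i, j)
      }
    }
    i <- best[1]; j <- best[2]
    for (a in clusters[[i]]) for (b in clusters[[j]]) {
      coph[a, b] <- coph[b, a] <- bestv
    }
    # UPGMA: unweighted average over member pairs
    merged <- c(clusters[[i]], clusters[[j]])
    for (k in idx) {
      if (k == i || k == j) next
      dd[i, k] <- dd[k, i] <-
        mean(d[merged, clusters[[k]], drop = FALSE])
    }
    clusters[[i]] <- merged
    active[j] <- FALSE
    dd[j, ] <- dd[, j] <- Inf
  }
  coph
}

# Exact two-sided permutation test on the difference of means.
oracle_permutation_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  obs <- abs(mean(a) - mean(b))
  idx <- utils::combn(n, length(a))
  stats <- apply(idx, 2, function(k) {
    abs(mean(pooled[k]) - mean(pooled[-k]))
  })
  mean(stats >= obs - 1e-12)
}

# Random bipartite peptide-protein fixture for grouping checks.
random_psm_fixture <- function(n_proteins, n_peptides, share_prob = 0.3,
                               seed = 1) {
  set.seed(seed)
  acc <- sprintf("P%03d", seq_len(n_proteins))
  rows <- lapply(seq_len(n_peptides), function(i) {
    k <- if (stats::runif(1) < share_prob) sample(2:min(3, n_proteins), 1) else 1
    data.frame(peptide_sequence = sprintf("pep%03d", i),
               protein_accession = sample(acc, k),
               stringsAsFactors = FALSE)
  })
  inc <- do.call(rbind, rows)
  # ensure every protein has at least two peptides so filtering keeps all
  extra <- do.call(rbind, lapply(seq_along(acc), function(i) {
    data.frame(peptide_sequence = sprintf("anchor%03d_%d", i, 1:2),
               protein_accession = acc[i], stringsAsFactors = FALSE)
  }))
  inc <- rbind(inc, extra)
  data.frame(peptide_sequence = inc$peptide_sequence,
             peptide_evalue = 1e-4,
             protein_accession = inc$protein_accession,
             protein_evalue = 1e-6,
             sample_id = "S1",
             spectra = 1L,
             stringsAsFactors = FALSE)
}

# Minimal emotionality-score table builder for classification tests.
make_scores <- function(ids, pre, post, group = "CORT/Flx") {
  rbind(
    data.frame(animal_id = ids, group = group, session = 1L,
               emotionality = pre, stringsAsFactors = FALSE),
    data.frame(animal_id = ids, group = group, session = 2L,
               emotionality = post, stringsAsFactors = FALSE)
  )
}
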