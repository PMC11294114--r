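# Shared fixture builders and independent oracles. Oracles are deliberately
# brute-force and coded without reference to the package internals.

tiny_counts <- function() {
  tibble::tibble(feature_id = c("g1", "g2", "g3"),
                 s1 = c(2, 4, 8), s2 = c(4, 8, 16))
}

# unpooled two-group study: n samples per group, direct NB draws
two_group_study <- function(n_feat, n, mu, alpha, lfc = 0, seed = 1) {
  set.seed(seed)
  if (length(mu) == 1) mu <- rep(mu, n_feat)
  if (length(lfc) == 1) lfc <- rep(lfc, n_feat)
  mu_a <- mu * 2^lfc
  ya <- matrix(stats::rnbinom(n_feat * n, mu = rep(mu_a, n), size = 1 / alpha), nrow = n_feat)
  yb <- matrix(stats::rnbinom(n_feat * n, mu = rep(mu, n), size = 1 / alpha), nrow = n_feat)
  y <- cbind(ya, yb)
  colnames(y) <- paste0("s", seq_len(2 * n))
  counts <- dplyr::bind_cols(
    tibble::tibble(feature_id = sprintf("f%05d", seq_len(n_feat))),
    tibble::as_tibble(y)
  )
  samples <- tibble::tibble(
    sample_id = colnames(y), tissue = "CX",
    genotype = rep(c("TS", "WT"), each = n), treatment = "nt",
    pooled_mouse_ids = paste0("m", seq_len(2 * n))
  )
  samples$group <- group_label(samples$genotype, samples$treatment)
  list(counts = counts, samples = samples)
}

# step-up BH straight from the definition: padj_i = min_{k: p_(k) >= p_i}
# over thresholds, via the classic double loop
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(o == i)  # rank of p_i
    adj[i] <- min(1, min(p[o[r:m]] * m / (r:m)))
  }
  adj
}

# exact two-sided Mann-Whitney p by full enumeration of rank subsets
ranksum_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  idx <- utils::combn(n + m, n)
  ranks <- seq_len(n + m)
  us <- apply(idx, 2, function(ii) sum(ranks[ii]) - n * (n + 1) / 2)
  lower <- mean(us <= u_obs)
  upper <- mean(us >= u_obs)
  min(1, 2 * min(lower, upper))
}

# upper-tail hypergeometric by enumerating every draw of size n from N
hyper_oracle <- function(k, K, n, N) {
  members <- seq_len(K)
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d %in% members)) >= k)
}

# nearest gene by exhaustive all-pairs distance scan
nearest_oracle <- function(l1, genes, window = 1e5) {
  out <- list()
  for (i in seq_len(nrow(l1))) {
    cands <- list()
    for (j in seq_len(nrow(genes))) {
      if (l1$chrom[i] != genes$chrom[j]) next
      ov <- genes$start[j] < l1$end[i] && l1$start[i] < genes$end[j]
      gap <- max(0, max(l1$start[i], genes$start[j]) - min(l1$end[i], genes$end[j]))
      if (!ov && gap > window) next
      cands[[length(cands) + 1]] <- data.frame(
        gene_id = genes$feature_id[j],
        relation = if (ov) "intragenic" else "proximal",
        distance = if (ov) 0 else gap,
        start = genes$start[j]
      )
    }
    if (length(cands) == 0) {
      out[[i]] <- tibble::tibble(l1_id = l1$feature_id[i], gene_id = NA_character_,
                                 relation = "distal_none", distance = NA_real_)
      next
    }
    cd <- do.call(rbind, cands)
    cd <- cd[order(cd$relation != "intragenic", cd$distance, cd$start, cd$gene_id), ]
    out[[i]] <- tibble::tibble(l1_id = l1$feature_id[i], gene_id = cd$gene_id[1],
                               relation = cd$relation[1], distance = cd$distance[1])
  }
  dplyr::bind_rows(out)
}

# independently coded two-group Poisson GLM Wald fit (closed form: the
# log-link MLE of a saturated two-group model is the ratio of sums)
poisson_wald_oracle <- function(ya, yb, sa, sb, df) {
  ma <- sum(ya) / sum(sa)
  mb <- sum(yb) / sum(sb)
  beta <- log(ma) - log(mb)
  se <- sqrt(1 / (ma * sum(sa)) + 1 / (mb * sum(sb)))
  z <- beta / se
  list(log2fc = beta / log(2), z = z, p = 2 * stats::pt(-abs(z), df = df))
}

random_features <- function(n, chrom = "MMU1", type = "gene", seed = NULL,
                            max_pos = 1e6) {
  if (!is.null(seed)) set.seed(seed)
  start <- sort(sample.int(max_pos, n))
  len <- sample.int(5e4, n)
  tibble::tibble(
    feature_id = sprintf("%s%04d", ifelse(type == "gene", "g", "L"), seq_len(n)),
    feature_type = type, chrom = chrom, start = start, end = start + len,
    strand = ".", hsa21_ortholog = FALSE, biotype = ifelse(type == "gene", "protein_coding", "L1")
  )
}
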