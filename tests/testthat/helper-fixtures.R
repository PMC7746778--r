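## Shared fixtures and independent oracles, built in code.

## small function count table with groups/studies
tiny_function_table <- function(seed = 42, n_feat = 6, n_samp = 8) {
  set.seed(seed)
  m <- matrix(rpois(n_feat * n_samp, 20), n_feat, n_samp,
              dimnames = list(sprintf("ko:K%05d", seq_len(n_feat)),
                              sprintf("s%02d", seq_len(n_samp))))
  AbundanceTable(m,
                 group = rep(c("case", "control"), each = n_samp / 2),
                 study = rep(c("studyA", "studyB"), n_samp / 2))
}

## independent Benjamini-Hochberg step-up oracle (no p.adjust)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

## brute-force confusion-count oracle for set metrics
set_metrics_oracle <- function(pred, meas) {
  pred <- unique(pred); meas <- unique(meas)
  tp <- sum(pred %in% meas)
  fp <- sum(!pred %in% meas)
  fn <- sum(!meas %in% pred)
  P <- if (tp + fp) tp / (tp + fp) else 0
  R <- if (tp + fn) tp / (tp + fn) else 0
  f1 <- if (P + R) 2 * P * R / (P + R) else 0
  list(tp = tp, fp = fp, fn = fn, precision = P, recall = R, f1 = f1)
}

## naive triple-loop CMP oracle: routes each function to its reactions
## (direct edges, else EC route; reaction features resolve as themselves)
## and accumulates coefficient-weighted abundances
cmp_oracle <- function(table, ref) {
  m <- abundances(table)
  out <- list()
  for (f in rownames(m)) {
    rxns <- if (f %in% names(ref@rxnToCpd)) f else {
      direct <- ref@koToRxn[[f]]
      if (!is.null(direct) && length(direct)) direct
      else {
        ecs <- ref@koToEc[[f]]
        if (is.null(ecs)) character(0)
        else unlist(ref@ecToRxn[intersect(ecs, names(ref@ecToRxn))],
                    use.names = FALSE)
      }
    }
    for (r in intersect(rxns, names(ref@rxnToCpd))) {
      v <- ref@rxnToCpd[[r]]
      v[is.na(v)] <- 1
      for (c in names(v)) {
        if (is.null(out[[c]])) out[[c]] <- numeric(ncol(m))
        out[[c]] <- out[[c]] + v[[c]] * m[f, ]
      }
    }
  }
  if (!length(out)) return(matrix(numeric(0), 0, ncol(m)))
  res <- do.call(rbind, out)
  colnames(res) <- colnames(m)
  res[sort(rownames(res)), , drop = FALSE]
}

## records for a hand-checkable three-KO reference
toy_records <- function() {
  data.frame(
    kind = c("ko_to_rxn", "ko_to_rxn", "ko_to_rxn",
             rep("rxn_to_cpd", 6)),
    from = c("ko:K00001", "ko:K00002", "ko:K00002",
             "rxn:R00001", "rxn:R00001", "rxn:R00002", "rxn:R00002",
             "rxn:R00003", "rxn:R00003"),
    to = c("rxn:R00001", "rxn:R00002", "rxn:R00003",
           "cpd:C00001", "cpd:C00002", "cpd:C00002", "cpd:C00003",
           "cpd:C00003", "cpd:C00004"),
    coef = c(NA, NA, NA, -1, 1, -1, 1, -2, 1),
    stringsAsFactors = FALSE)
}
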