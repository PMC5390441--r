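# Independent oracles used across the suite. These deliberately avoid the
# package's own evaluation code paths.

# Truth-table oracle: render the tree as a base-R logical expression over
# x[1..k] and eval() it.
oracle_eval <- function(tree, assignment) {
  expr_text <- function(node) {
    if (node$type == "leaf") {
      e <- paste0("x[", node$index, "]")
      if (node$complement) paste0("!", e) else e
    } else {
      op <- if (node$op == "and") " & " else " | "
      paste0("(", expr_text(node$left), op, expr_text(node$right), ")")
    }
  }
  x <- assignment > 0
  eval(parse(text = expr_text(tree)))
}

all_assignments <- function(k) {
  as.matrix(expand.grid(rep(list(0:1), k)))
}

# Exhaustive enumeration of trees with up to 3 leaves over n_rules rules.
enumerate_small_trees <- function(n_rules) {
  leaves <- list()
  for (i in seq_len(n_rules)) {
    leaves <- c(leaves, list(logic_leaf(i, FALSE), logic_leaf(i, TRUE)))
  }
  two_leaf <- list()
  for (op in c("and", "or")) {
    for (a in leaves) for (b in leaves) {
      two_leaf <- c(two_leaf, list(logic_node(op, a, b)))
    }
  }
  trees <- c(leaves, two_leaf)
  for (op in c("and", "or")) {
    for (ab in two_leaf) for (c_ in leaves) {
      trees <- c(trees, list(logic_node(op, ab, c_)),
                 list(logic_node(op, c_, ab)))
    }
  }
  trees
}

random_tree <- function(n_rules, n_leaves) {
  nodes <- lapply(seq_len(n_leaves), function(i) {
    logic_leaf(sample.int(n_rules, 1), complement = runif(1) < 0.5)
  })
  while (length(nodes) > 1) {
    i <- sample.int(length(nodes) - 1, 1)
    nodes[[i]] <- logic_node(sample(c("and", "or"), 1),
                             nodes[[i]], nodes[[i + 1]])
    nodes[[i + 1]] <- NULL
  }
  nodes[[1]]
}

# Exhaustive cutoff oracle: scans observed values as well as midpoints and
# sentinels, and returns the maximal sensitivity + specificity.
cutoff_oracle <- function(v, y, direction) {
  s <- sort(unique(v))
  cands <- sort(unique(c(-Inf, s,
                         if (length(s) > 1) (utils::head(s, -1) + s[-1]) / 2,
                         Inf)))
  best <- -Inf
  best_cut <- NA_real_
  for (cut in cands) {
    pred <- if (direction == "gt") v > cut else v < cut
    obj <- sum(pred & y == 1) / sum(y == 1) +
      sum(!pred & y == 0) / sum(y == 0)
    if (obj > best + 1e-12) {
      best <- obj
      best_cut <- cut
    }
  }
  list(obj = best, cutoff = best_cut)
}
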