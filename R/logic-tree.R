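#' Logic trees
#'
#' A logic tree is a Boolean combination of rule indices: leaves reference a
#' rule (optionally complemented), internal nodes are binary AND/OR
#' operators. Trees are the model class fitted per target by [anneal()].
#'
#' @param index 1-based rule index.
#' @param complement Negate the leaf's rule value?
#' @return A `logic_tree` node.
#' @export
#' @examples
#' tr <- logic_or(logic_leaf(1), logic_leaf(2)) |> logic_and(logic_leaf(3))
#' evaluate_tree(tr, c(0, 1, 1))
logic_leaf <- function(index, complement = FALSE) {
  stopifnot(index >= 1)
  structure(list(type = "leaf", index = as.integer(index),
                 complement = isTRUE(complement)),
            class = "logic_tree")
}

#' @rdname logic_leaf
#' @param left,right Child nodes.
#' @param op `"and"` or `"or"`.
#' @export
logic_node <- function(op, left, right) {
  op <- match.arg(op, c("and", "or"))
  structure(list(type = "op", op = op, left = left, right = right),
            class = "logic_tree")
}

#' @rdname logic_leaf
#' @export
logic_and <- function(left, right) logic_node("and", left, right)

#' @rdname logic_leaf
#' @export
logic_or <- function(left, right) logic_node("or", left, right)

#' Evaluate a logic tree on binary rule values
#'
#' @param tree A `logic_tree`.
#' @param rule_values Binary vector (one tree evaluation) or 0/1 matrix with
#'   one column per rule (one evaluation per row).
#' @return A logical scalar, or a logical vector with one element per matrix
#'   row.
#' @export
evaluate_tree <- function(tree, rule_values) {
  if (!is.matrix(rule_values)) {
    rule_values <- matrix(rule_values, nrow = 1)
    return(eval_node(tree, rule_values)[1])
  }
  eval_node(tree, rule_values)
}

eval_node <- function(node, m) {
  if (node$type == "leaf") {
    if (node$index > ncol(m)) {
      abort(paste0("leaf references rule ", node$index,
                   " but only ", ncol(m), " rules supplied"))
    }
    v <- m[, node$index] > 0
    if (node$complement) !v else v
  } else if (node$op == "and") {
    eval_node(node$left, m) & eval_node(node$right, m)
  } else {
    eval_node(node$left, m) | eval_node(node$right, m)
  }
}

#' Count leaves / list leaves of a logic tree
#'
#' @param tree A `logic_tree`.
#' @return `tree_leaf_count()`: integer. `tree_leaves()`: tibble with one
#'   row per leaf (`index`, `complement`).
#' @export
tree_leaf_count <- function(tree) {
  if (tree$type == "leaf") return(1L)
  tree_leaf_count(tree$left) + tree_leaf_count(tree$right)
}

#' @rdname tree_leaf_count
#' @export
tree_leaves <- function(tree) {
  if (tree$type == "leaf") {
    return(tibble::tibble(index = tree$index, complement = tree$complement))
  }
  dplyr::bind_rows(tree_leaves(tree$left), tree_leaves(tree$right))
}

# Paths address nodes as integer vectors of 1 (left) / 2 (right) child
# steps from the root; integer(0) is the root itself.
node_paths <- function(node, path = integer(0)) {
  if (node$type == "leaf") {
    return(list(list(path = path, type = "leaf")))
  }
  c(list(list(path = path, type = "op")),
    node_paths(node$left, c(path, 1L)),
    node_paths(node$right, c(path, 2L)))
}

get_node <- function(tree, path) {
  for (step in path) tree <- if (step == 1L) tree$left else tree$right
  tree
}

set_node <- function(tree, path, value) {
  if (length(path) == 0) return(value)
  slot <- if (path[1] == 1L) "left" else "right"
  tree[[slot]] <- set_node(tree[[slot]], path[-1], value)
  tree
}

#' Propose one random tree move
#'
#' Draws uniformly among the applicable ones of the six elementary moves of
#' the annealing search: alternate a leaf (change its rule or toggle its
#' complement), alternate an operator (AND <-> OR), grow a branch (replace a
#' leaf by a node pairing it with a new random leaf), prune a branch
#' (replace an internal node by one of its children), split a leaf (the
#' mirror-attachment variant of growing), and delete a leaf (promote its
#' sibling). On a single-leaf tree, prune and delete are inapplicable and
#' excluded from the draw. The input tree is not modified. Draws come from
#' the R random number stream; seed control belongs to the caller.
#'
#' @param tree A `logic_tree`.
#' @param n_rules Number of available rules.
#' @return A new `logic_tree` differing from `tree` by exactly one move.
#' @export
propose_move <- function(tree, n_rules) {
  stopifnot(n_rules >= 1)
  info <- node_paths(tree)
  leaf_paths <- purrr::map(purrr::keep(info, ~ .x$type == "leaf"), "path")
  op_paths <- purrr::map(purrr::keep(info, ~ .x$type == "op"), "path")
  moves <- c("alternate_leaf", "grow_branch", "split_leaf")
  if (length(op_paths) > 0) {
    moves <- c(moves, "alternate_operator", "prune_branch", "delete_leaf")
  }
  move <- moves[sample.int(length(moves), 1)]
  random_leaf <- function() {
    logic_leaf(sample.int(n_rules, 1), complement = runif(1) < 0.5)
  }
  pick <- function(paths) paths[[sample.int(length(paths), 1)]]
  switch(move,
    alternate_leaf = {
      path <- pick(leaf_paths)
      leaf <- get_node(tree, path)
      # uniform over the other (rule, complement) combinations
      k <- sample.int(2 * n_rules - 1, 1)
      current <- (leaf$index - 1) * 2 + as.integer(leaf$complement)
      chosen <- (current + k) %% (2 * n_rules)
      set_node(tree, path,
               logic_leaf(chosen %/% 2 + 1, complement = chosen %% 2 == 1))
    },
    alternate_operator = {
      path <- pick(op_paths)
      node <- get_node(tree, path)
      node$op <- if (node$op == "and") "or" else "and"
      set_node(tree, path, node)
    },
    grow_branch = {
      path <- pick(leaf_paths)
      old <- get_node(tree, path)
      set_node(tree, path,
               logic_node(c("and", "or")[sample.int(2, 1)], old, random_leaf()))
    },
    split_leaf = {
      path <- pick(leaf_paths)
      old <- get_node(tree, path)
      set_node(tree, path,
               logic_node(c("and", "or")[sample.int(2, 1)], random_leaf(), old))
    },
    prune_branch = {
      path <- pick(op_paths)
      node <- get_node(tree, path)
      set_node(tree, path, if (runif(1) < 0.5) node$left else node$right)
    },
    delete_leaf = {
      # remove a random leaf that has a parent; its sibling is promoted
      path <- pick(leaf_paths[lengths(leaf_paths) > 0])
      parent_path <- path[-length(path)]
      parent <- get_node(tree, parent_path)
      sibling <- if (path[length(path)] == 1L) parent$right else parent$left
      set_node(tree, parent_path, sibling)
    }
  )
}

#' Render / parse the Boolean expression of a logic tree
#'
#' `tree_to_expression()` renders a fully parenthesized infix expression
#' with symbols `AND`, `OR`, `NOT`; `parse_expression()` parses such an
#' expression back into an equivalent tree (round-trip identity).
#'
#' @param tree A `logic_tree`.
#' @param rule_ids Character vector of rule identifiers; leaf `i` renders as
#'   `rule_ids[i]`.
#' @return A character scalar / a `logic_tree`.
#' @export
#' @examples
#' tr <- logic_and(logic_or(logic_leaf(1), logic_leaf(2)), logic_leaf(3))
#' tree_to_expression(tr, c("R1", "R2", "R3"))
tree_to_expression <- function(tree, rule_ids) {
  if (tree$type == "leaf") {
    if (tree$index > length(rule_ids)) {
      abort("rule_ids does not cover all leaf indices")
    }
    id <- rule_ids[tree$index]
    return(if (tree$complement) paste0("(NOT ", id, ")") else id)
  }
  op <- if (tree$op == "and") "AND" else "OR"
  paste0("(", tree_to_expression(tree$left, rule_ids), " ", op, " ",
         tree_to_expression(tree$right, rule_ids), ")")
}

#' @rdname tree_to_expression
#' @param text Expression string produced by `tree_to_expression()`.
#' @export
parse_expression <- function(text, rule_ids) {
  tokens <- stringr::str_extract_all(
    text, "\\(|\\)|AND|OR|NOT|[^\\s()]+")[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  take <- function() {
    tok <- peek()
    pos <<- pos + 1L
    tok
  }
  parse_node <- function() {
    tok <- take()
    if (is.na(tok)) abort("unexpected end of expression")
    if (tok == "(") {
      if (identical(peek(), "NOT")) {
        take()
        inner <- parse_node()
        if (inner$type != "leaf") abort("NOT applies to a leaf")
        inner$complement <- !inner$complement
        if (take() != ")") abort("expected ')'")
        return(inner)
      }
      left <- parse_node()
      op <- take()
      if (!op %in% c("AND", "OR")) abort(paste0("expected operator, got ", op))
      right <- parse_node()
      if (take() != ")") abort("expected ')'")
      return(logic_node(tolower(op), left, right))
    }
    idx <- match(tok, rule_ids)
    if (is.na(idx)) abort(paste0("unknown rule id: ", tok))
    logic_leaf(idx)
  }
  out <- parse_node()
  if (pos <= length(tokens)) abort("trailing tokens in expression")
  out
}

#' @export
format.logic_tree <- function(x, ...) {
  n <- max(tree_leaves(x)$index)
  tree_to_expression(x, paste0("R", seq_len(n)))
}

#' @export
print.logic_tree <- function(x, ...) {
  cat("<logic_tree> ", format(x), "\n", sep = "")
  invisible(x)
}
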