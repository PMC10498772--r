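# Parameter trees: nested named lists whose leaves are numeric arrays.
# Gradients, Adam moments and parameter updates all share one structure,
# so elementwise recursion is the only machinery needed.

isLeaf <- function(x) is.numeric(x)

# Apply f elementwise over corresponding leaves of one or more trees with
# identical structure.
treeMap <- function(f, tree, ...) {
  rest <- list(...)
  if (isLeaf(tree)) {
    return(do.call(f, c(list(tree), lapply(rest, identity))))
  }
  out <- vector("list", length(tree))
  names(out) <- names(tree)
  for (i in seq_along(tree)) {
    out[[i]] <- do.call(treeMap, c(list(f, tree[[i]]), lapply(rest, `[[`, i)))
  }
  out
}

treeZero <- function(tree) treeMap(function(x) x * 0, tree)

treeAdd <- function(a, b) treeMap(`+`, a, b)

# Total number of scalar parameters in a tree.
treeCount <- function(tree) {
  if (isLeaf(tree)) return(length(tree))
  sum(vapply(tree, treeCount, numeric(1)))
}

# Sum of squares across all leaves (gradient-norm diagnostics).
treeSumSq <- function(tree) {
  if (isLeaf(tree)) return(sum(tree^2))
  sum(vapply(tree, treeSumSq, numeric(1)))
}

# Flatten to a single numeric vector (checkpoint digests, bitwise equality).
treeFlatten <- function(tree) {
  if (isLeaf(tree)) return(as.numeric(tree))
  unlist(lapply(tree, treeFlatten), use.names = FALSE)
}

# Evaluate expr with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards. All package-level determinism funnels through
# this helper.
withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hadSeed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647L))
  expr
}
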