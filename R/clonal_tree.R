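# Rooted mutation trees are stored as a named integer parent vector over
# the m mutation nodes; 0 denotes the implicit wild-type root. Node i's
# mutations are those on the path root -> i.

validate_parent <- function(parent) {
  m <- length(parent)
  if (m < 1L) stop("tree must have at least one mutation node")
  if (is.null(names(parent)) || anyDuplicated(names(parent)))
    stop("parent vector must have unique character names")
  if (any(parent < 0L | parent > m) || any(parent == seq_len(m)))
    stop("parent entries must lie in 0..m and differ from the node index")
  # acyclicity: every node must reach the root
  for (i in seq_len(m)) {
    v <- i; steps <- 0L
    while (v != 0L) {
      v <- parent[v]; steps <- steps + 1L
      if (steps > m) stop("parent vector contains a cycle")
    }
  }
  invisible(parent)
}

# (m+1) x m matrix: row a+1 gives the expected genotype of a cell
# attached at node a (row 1 = root, all zero).
attachment_genotypes <- function(parent) {
  m <- length(parent)
  E <- matrix(0L, m + 1L, m, dimnames = list(NULL, names(parent)))
  for (a in seq_len(m)) {
    v <- a
    while (v != 0L) {
      E[a + 1L, v] <- 1L
      v <- parent[v]
    }
  }
  E
}

#' Encode an integrated genotype matrix for tree inference
#'
#' Maps integrated calls to binary mutation characters. A non-LOH variant
#' becomes one character (WT -> 0, HET or HOM -> 1, anything else ->
#' missing). A variant subject to loss of heterozygosity is split into
#' two allele characters so that homozygosity (loss of the WT allele) is
#' representable: WT -> (0,0), HET -> (1,0), HOM -> (1,1), otherwise
#' (missing, missing).
#'
#' @param gm A `genotype_matrix` (see [integrate_calls()]) or a plain
#'   character matrix of integrated calls.
#' @param loh_variants Variant ids to split into allele pairs.
#' @return Integer matrix cells x characters in {0, 1, NA}; allele
#'   characters are named `<variant>.a1` / `<variant>.a2`.
#' @export
encode_matrix <- function(gm, loh_variants = character(0)) {
  missing_loh <- setdiff(loh_variants, colnames(gm))
  if (length(missing_loh))
    stop(sprintf("loh variant(s) absent from matrix: %s",
                 paste(missing_loh, collapse = ", ")))
  cols <- list()
  for (v in colnames(gm)) {
    calls <- gm[, v]
    if (v %in% loh_variants) {
      a1 <- ifelse(calls %in% c("HET", "HOM"), 1L,
            ifelse(calls == "WT", 0L, NA_integer_))
      a2 <- ifelse(calls == "HOM", 1L,
            ifelse(calls %in% c("WT", "HET"), 0L, NA_integer_))
      cols[[paste0(v, ".a1")]] <- a1
      cols[[paste0(v, ".a2")]] <- a2
    } else {
      cols[[v]] <- ifelse(calls %in% c("HET", "HOM"), 1L,
                   ifelse(calls == "WT", 0L, NA_integer_))
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(gm)
  out
}

#' Log-likelihood of a mutation tree
#'
#' Single-cell mutation-tree likelihood under the false-positive /
#' allelic-dropout error model: P(1|0) = fd, P(0|1) = ad. Each cell
#' attaches to any of the m+1 tree nodes (uniform prior including the
#' wild-type root); its marginal likelihood is the mean over attachments
#' of the product over characters of the observation probabilities given
#' the genotype expected on that attachment's root path. Missing entries
#' contribute a factor of 1. The total is the sum over cells of the log
#' marginal, computed in log space.
#'
#' @param mm Cells x characters matrix in {0, 1, NA}.
#' @param parent Named parent vector over the matrix's characters.
#' @param fd False-positive rate P(observe 1 | true 0), default 0.001.
#' @param ad Allelic-dropout rate P(observe 0 | true 1), default 0.01.
#' @return Total log-likelihood (natural log).
#' @export
tree_loglik <- function(mm, parent, fd = 0.001, ad = 0.01) {
  validate_parent(parent)
  if (!setequal(colnames(mm), names(parent)))
    stop("matrix characters do not match tree nodes")
  mm <- mm[, names(parent), drop = FALSE]
  E <- attachment_genotypes(parent)
  # log P(obs | expected): columns follow the characters; probabilities
  # are clamped at 1e-300 so degenerate rates (fd or ad of 0) stay finite
  lg <- function(p) log(pmax(p, 1e-300))
  M1 <- E * lg(1 - ad) + (1 - E) * lg(fd)     # obs = 1
  M0 <- E * lg(ad) + (1 - E) * lg(1 - fd)     # obs = 0
  X1 <- (!is.na(mm)) & mm == 1L
  X0 <- (!is.na(mm)) & mm == 0L
  storage.mode(X1) <- storage.mode(X0) <- "double"
  ll <- X1 %*% t(M1) + X0 %*% t(M0)           # cells x (m+1)
  mx <- apply(ll, 1, max)
  sum(mx + log(rowMeans(exp(ll - mx))))
}

# Decode a Prufer sequence over labels 0..m into the parent vector of the
# tree rooted at 0.
decode_prufer <- function(pr, m, characters) {
  n <- m + 1L
  deg <- rep(1L, n)
  for (x in pr) deg[x + 1L] <- deg[x + 1L] + 1L
  edges <- matrix(0L, 2, n - 1L)
  for (k in seq_along(pr)) {
    leaf <- which(deg == 1L)[1] - 1L
    edges[, k] <- c(leaf, pr[k])
    deg[leaf + 1L] <- 0L
    deg[pr[k] + 1L] <- deg[pr[k] + 1L] - 1L
  }
  edges[, n - 1L] <- which(deg == 1L) - 1L
  # orient edges away from root 0
  adj <- vector("list", n)
  for (k in seq_len(ncol(edges))) {
    a <- edges[1, k] + 1L; b <- edges[2, k] + 1L
    adj[[a]] <- c(adj[[a]], b - 1L)
    adj[[b]] <- c(adj[[b]], a - 1L)
  }
  parent <- integer(m)
  queue <- 0L; seen <- c(TRUE, rep(FALSE, m))
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v + 1L]]) if (!seen[w + 1L]) {
      seen[w + 1L] <- TRUE
      parent[w] <- v
      queue <- c(queue, w)
    }
  }
  stats::setNames(parent, characters)
}

# All rooted labeled trees on nodes {0..m} with root 0, enumerated by
# decoding every Prufer sequence over the m+1 labels (Cayley:
# (m+1)^(m-1) trees).
enumerate_parent_vectors <- function(m, characters = NULL) {
  if (is.null(characters)) characters <- paste0("M", seq_len(m))
  if (m == 1L) return(list(stats::setNames(0L, characters)))
  seqs <- as.matrix(expand.grid(rep(list(0:m), m - 1L)))
  lapply(seq_len(nrow(seqs)), function(i)
    decode_prufer(seqs[i, ], m, characters))
}

#' Infer the maximum-likelihood mutation tree
#'
#' Finds the rooted mutation tree maximizing [tree_loglik()]. In
#' `exhaustive` mode all (m+1)^(m-1) rooted labeled trees are enumerated
#' (m <= 7); co-optimal trees are all returned, ordered by lexicographic
#' parent vector. In `search` mode a seeded steepest-ascent hill climb
#' over prune-and-reattach moves is run from random starting trees with
#' the given number of restarts, returning the best local optimum found.
#'
#' @param mm Cells x characters matrix in {0, 1, NA}.
#' @param fd,ad Error rates (see [tree_loglik()]).
#' @param mode `"exhaustive"` or `"search"`.
#' @param seed Seed for search-mode restarts.
#' @param restarts Number of hill-climb restarts (default 1).
#' @param tol Log-likelihood tolerance for co-optimality.
#' @return An object of class `clone_tree_fit`: the best parent vector,
#'   its log-likelihood, all co-optimal parent vectors (exhaustive mode),
#'   and the error rates.
#' @export
infer_tree <- function(mm, fd = 0.001, ad = 0.01,
                       mode = c("exhaustive", "search"), seed = 1L,
                       restarts = 1L, tol = 1e-9) {
  mode <- match.arg(mode)
  chars <- colnames(mm)
  m <- length(chars)
  if (mode == "exhaustive") {
    if (m > 7L)
      stop("exhaustive enumeration is limited to m <= 7; use mode = 'search'")
    trees <- enumerate_parent_vectors(m, chars)
    ll <- vapply(trees, function(p) tree_loglik(mm, p, fd, ad), numeric(1))
    best <- max(ll)
    co <- trees[ll >= best - tol]
    ord <- order(vapply(co, function(p) paste(p, collapse = ","),
                        character(1)))
    co <- co[ord]
    fit <- list(parent = co[[1]], loglik = best, co_optimal = co,
                fd = fd, ad = ad, mode = mode, n_cells = nrow(mm),
                n_trees_scored = length(trees))
  } else {
    set.seed(seed)
    best_p <- NULL; best_ll <- -Inf
    for (r in seq_len(restarts)) {
      p <- random_parent_vector(m, chars)
      ll <- tree_loglik(mm, p, fd, ad)
      repeat {
        moves <- neighbor_trees(p)
        lls <- vapply(moves, function(q) tree_loglik(mm, q, fd, ad),
                      numeric(1))
        if (!length(lls) || max(lls) <= ll + tol) break
        k <- which.max(lls)
        p <- moves[[k]]; ll <- lls[k]
      }
      if (ll > best_ll) { best_ll <- ll; best_p <- p }
    }
    fit <- list(parent = best_p, loglik = best_ll, co_optimal = list(best_p),
                fd = fd, ad = ad, mode = mode, n_cells = nrow(mm),
                restarts = restarts)
  }
  class(fit) <- "clone_tree_fit"
  fit
}

# uniform random rooted tree via a random Prufer sequence
random_parent_vector <- function(m, characters) {
  if (m == 1L) return(stats::setNames(0L, characters))
  decode_prufer(sample(0:m, m - 1L, replace = TRUE), m, characters)
}

#' Draw a uniformly random rooted mutation tree
#'
#' Samples uniformly from the (m+1)^(m-1) rooted labeled trees on m
#' mutation nodes plus the wild-type root (via a random Prufer
#' sequence). Uses the current RNG state.
#'
#' @param m Number of mutation nodes.
#' @param characters Optional character names (default `M1..Mm`).
#' @return A named parent vector (see [tree_loglik()]).
#' @export
random_tree <- function(m, characters = NULL) {
  if (is.null(characters)) characters <- paste0("M", seq_len(m))
  stopifnot(length(characters) == m)
  random_parent_vector(m, characters)
}

# exchange the tree positions of nodes i and j (label swap)
swap_labels <- function(parent, i, j) {
  m <- length(parent)
  perm <- seq_len(m)
  perm[c(i, j)] <- c(j, i)
  q <- parent
  for (k in seq_len(m)) {
    p <- parent[k]
    q[perm[k]] <- if (p == 0L) 0L else perm[p]
  }
  q
}

# hill-climb neighborhood: prune-and-reattach of one node (with its
# subtree) under any non-descendant, plus all pairwise label swaps --
# reattach moves alone leave deep local optima on chain topologies
neighbor_trees <- function(parent) {
  m <- length(parent)
  E <- attachment_genotypes(parent)   # j desc of i iff E[j+1, i] == 1
  out <- list()
  for (i in seq_len(m)) {
    desc <- which(E[-1, i] == 1L)     # nodes whose path contains i (incl. i)
    for (new_p in setdiff(0:m, c(parent[i], desc))) {
      q <- parent
      q[i] <- new_p
      out[[length(out) + 1L]] <- q
    }
  }
  if (m > 1L)
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m)
      out[[length(out) + 1L]] <- swap_labels(parent, i, j)
  out
}

#' Mutation acquisition order implied by a tree
#'
#' Returns every (earlier, later) ancestor relation of the tree's
#' mutation nodes, plus the pairs that are unordered because they lie on
#' different branches (independently acquired).
#'
#' @param x A `clone_tree_fit` or a named parent vector.
#' @return `list(ordered, branching)`: data.frames of (earlier, later)
#'   and of incomparable pairs.
#' @export
mutation_order <- function(x) {
  parent <- if (inherits(x, "clone_tree_fit")) x$parent else x
  validate_parent(parent)
  m <- length(parent)
  chars <- names(parent)
  E <- attachment_genotypes(parent)
  anc <- function(j) setdiff(which(E[j + 1L, ] == 1L), j)
  ordered <- list(); branching <- list()
  for (j in seq_len(m)) for (i in anc(j))
    ordered[[length(ordered) + 1L]] <- data.frame(
      earlier = chars[i], later = chars[j], stringsAsFactors = FALSE)
  if (m > 1L) for (i in seq_len(m - 1L)) for (j in (i + 1L):m)
    if (E[j + 1L, i] == 0L && E[i + 1L, j] == 0L)
      branching[[length(branching) + 1L]] <- data.frame(
        a = chars[i], b = chars[j], stringsAsFactors = FALSE)
  list(ordered = if (length(ordered)) do.call(rbind, ordered) else
         data.frame(earlier = character(0), later = character(0)),
       branching = if (length(branching)) do.call(rbind, branching) else
         data.frame(a = character(0), b = character(0)))
}

#' Newick representation of a mutation tree
#'
#' Mutations label internal nodes; the wild-type root is labeled `WT`.
#'
#' @param x A `clone_tree_fit` or a named parent vector.
#' @return A Newick string.
#' @export
tree_newick <- function(x) {
  parent <- if (inherits(x, "clone_tree_fit")) x$parent else x
  validate_parent(parent)
  chars <- names(parent)
  kids <- function(v) which(parent == v)
  rec <- function(v) {
    lab <- if (v == 0L) "WT" else chars[v]
    ch <- kids(v)
    if (!length(ch)) return(lab)
    paste0("(", paste(vapply(sort(ch), rec, character(1)),
                      collapse = ","), ")", lab)
  }
  paste0(rec(0L), ";")
}

#' Write a tree as parent-vector JSON
#'
#' @param x A `clone_tree_fit` or a named parent vector.
#' @param path File path.
#' @export
write_tree_json <- function(x, path) {
  parent <- if (inherits(x, "clone_tree_fit")) x$parent else x
  jsonlite::write_json(as.list(parent), path, auto_unbox = TRUE)
  invisible(path)
}

#' @export
print.clone_tree_fit <- function(x, ...) {
  cat("Maximum-likelihood mutation tree\n")
  cat(sprintf("  characters: %s\n", paste(names(x$parent), collapse = ", ")))
  cat(sprintf("  topology:   %s\n", tree_newick(x)))
  cat(sprintf("  log-likelihood: %.4f  (%d cells, fd=%g, ad=%g, %s mode)\n",
              x$loglik, x$n_cells, x$fd, x$ad, x$mode))
  if (length(x$co_optimal) > 1L)
    cat(sprintf("  %d co-optimal topologies\n", length(x$co_optimal)))
  invisible(x)
}

#' @export
summary.clone_tree_fit <- function(object, ...) {
  print(object)
  mo <- mutation_order(object)
  if (nrow(mo$ordered)) {
    cat("  acquisition order:\n")
    for (k in seq_len(nrow(mo$ordered)))
      cat(sprintf("    %s before %s\n", mo$ordered$earlier[k],
                  mo$ordered$later[k]))
  }
  if (nrow(mo$branching)) {
    cat("  independently acquired (branching):\n")
    for (k in seq_len(nrow(mo$branching)))
      cat(sprintf("    %s | %s\n", mo$branching$a[k], mo$branching$b[k]))
  }
  invisible(mo)
}

#' @export
logLik.clone_tree_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$parent),
            nobs = object$n_cells, class = "logLik")
}

#' @export
plot.clone_tree_fit <- function(x, ...) {
  tr <- ape::read.tree(text = tree_newick(x))
  ape::plot.phylo(tr, show.node.label = TRUE, ...)
  invisible(tr)
}
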