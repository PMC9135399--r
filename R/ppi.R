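#' Undirected protein-protein interaction network
#'
#' Simple undirected graph over protein IDs stored as a canonical edge table
#' with a degree index and logarithmic (base-2) degree bins used by the
#' degree-preserving randomization.
#'
#' @param edges Two-column data.frame or character matrix of interacting
#'   protein pairs. Self-loops are rejected; duplicate (undirected) edges are
#'   collapsed with a warning.
#' @return An object of class \code{interaction_network} with elements
#'   \code{edges} (character matrix, endpoints sorted within row),
#'   \code{nodes}, \code{degree} (named integer) and \code{bin} (named
#'   integer, floor(log2(degree))).
#' @export
interaction_network <- function(edges) {
  e <- as.matrix(edges)[, 1:2, drop = FALSE]
  mode(e) <- "character"
  if (any(e[, 1] == e[, 2])) {
    stop(sprintf("self-loop edge(s) not allowed (e.g. %s)",
                 e[which(e[, 1] == e[, 2])[1], 1]))
  }
  swap <- e[, 1] > e[, 2]
  e[swap, ] <- e[swap, 2:1]
  key <- paste(e[, 1], e[, 2], sep = "\r")
  if (anyDuplicated(key)) {
    warning(sprintf("%d duplicate edge(s) collapsed", sum(duplicated(key))),
            call. = FALSE)
    e <- e[!duplicated(key), , drop = FALSE]
  }
  deg <- table(c(e[, 1], e[, 2]))
  degree <- setNames(as.integer(deg), names(deg))
  structure(list(edges = unname(e), nodes = names(degree), degree = degree,
                 bin = setNames(as.integer(floor(log2(degree))), names(degree))),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Count physical interactions between two protein sets
#'
#' Number of network edges with one endpoint in A and the other in B. Each
#' edge is counted once (an edge with both endpoints in the intersection
#' contributes one). Proteins absent from the network contribute nothing.
#'
#' @param setA,setB Character vectors of protein IDs.
#' @param net An [interaction_network()].
#' @return Integer count.
#' @export
count_cross_interactions <- function(setA, setB, net) {
  e <- net$edges
  a1 <- e[, 1] %in% setA
  a2 <- e[, 2] %in% setA
  b1 <- e[, 1] %in% setB
  b2 <- e[, 2] %in% setB
  sum((a1 & b2) | (a2 & b1))
}

# Sample one degree-matched replacement for protein p, excluding `taken`.
# Starts in the protein's own log2-degree bin and widens to adjacent bins
# when the bin is exhausted.
sample_degree_match <- function(p, net, bin_index, taken) {
  b <- net$bin[[p]]
  bins <- sort(unique(net$bin))
  for (width in 0:length(bins)) {
    cand <- unlist(bin_index[as.character(bins[abs(bins - b) <= width])],
                   use.names = FALSE)
    cand <- cand[!(cand %in% taken) & cand != p]
    if (length(cand)) return(cand[sample.int(length(cand), 1L)])
  }
  stop(sprintf("degree bins exhausted for protein %s", p))
}

#' Degree-preserving randomization test for cross-set interaction counts
#'
#' Tests whether the observed number of interactions between setA (the
#' aneuploid differentially abundant proteins) and a fixed setB exceeds
#' chance. Each iteration replaces every member of setA with a distinct
#' network protein drawn uniformly from its logarithmic degree bin (widening
#' to adjacent bins when exhausted, the replaced protein itself excluded),
#' then recounts interactions with setB. The p-value uses a pseudocount:
#' p = (1 + #\{null >= observed\}) / (n_iter + 1).
#'
#' @inheritParams count_cross_interactions
#' @param n_iter Number of randomizations (>= 100).
#' @param seed Optional integer seed for reproducibility.
#' @param p_type "pseudocount" (default) or "raw" (k / n_iter).
#' @return list(observed, null (numeric vector), p, n_iter, setA_used).
#' @export
degree_preserving_test <- function(setA, setB, net, n_iter = 1000, seed = NULL,
                                   p_type = c("pseudocount", "raw")) {
  p_type <- match.arg(p_type)
  if (n_iter < 100) stop("n_iter must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  setA <- unique(as.character(setA))
  missing <- setdiff(setA, net$nodes)
  if (length(missing)) {
    warning(sprintf("%d setA proteins absent from the network dropped",
                    length(missing)), call. = FALSE)
    setA <- setdiff(setA, missing)
  }
  if (!length(setA)) stop("no setA proteins present in the network")
  observed <- count_cross_interactions(setA, setB, net)
  bin_index <- split(net$nodes, as.character(net$bin))
  e <- net$edges
  b1 <- e[, 1] %in% setB
  b2 <- e[, 2] %in% setB
  null <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    repl <- character(length(setA))
    for (j in seq_along(setA)) {
      repl[j] <- sample_degree_match(setA[j], net, bin_index, repl[seq_len(j - 1L)])
    }
    a1 <- e[, 1] %in% repl
    a2 <- e[, 2] %in% repl
    null[it] <- sum((a1 & b2) | (a2 & b1))
  }
  p <- if (p_type == "pseudocount") (1 + sum(null >= observed)) / (n_iter + 1)
       else sum(null >= observed) / n_iter
  list(observed = observed, null = null, p = p, n_iter = n_iter,
       setA_used = setA)
}

#' Read an undirected edge list from a TSV file
#'
#' Two ID columns, no header requirement beyond the first two columns being
#' the endpoints. Self-loops are rejected with the offending line number.
#'
#' @param path File path.
#' @return An [interaction_network()].
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop(sprintf("edge list %s needs two columns", path))
  loop <- which(df[[1]] == df[[2]])
  if (length(loop)) {
    stop(sprintf("self-loop in %s at line %d (%s)", path, loop[1] + 1L,
                 df[[1]][loop[1]]))
  }
  interaction_network(df[, 1:2])
}
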