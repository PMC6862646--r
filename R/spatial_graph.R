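# Region adjacency structure, intrinsic MRF precision, the ICAR
# conditional prior, and Moran's I with permutation inference.

#' Construct a region adjacency graph
#'
#' @param region_ids character vector of unique region labels (size S).
#' @param edges two-column matrix or data.frame of undirected neighbor
#'   pairs (labels).  Self-loops are an error; each pair is stored
#'   symmetrically.
#' @return a `region_graph`: list with `region_ids`, `nbrs` (named list
#'   of neighbor label vectors), and `N` (neighbor counts).
#' @export
region_graph <- function(region_ids, edges) {
  region_ids <- as.character(region_ids)
  if (anyDuplicated(region_ids)) stop("duplicate region labels")
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must have two columns")
  storage.mode(edges) <- "character"
  if (any(edges[, 1] == edges[, 2]))
    stop("self-loop in adjacency: ", edges[edges[, 1] == edges[, 2], 1][1])
  unknown <- setdiff(unique(c(edges)), region_ids)
  if (length(unknown)) stop("edge references unknown region(s): ",
                            paste(unknown, collapse = ", "))
  nbrs <- setNames(lapply(region_ids, function(s) {
    sort(unique(c(edges[edges[, 1] == s, 2], edges[edges[, 2] == s, 1])))
  }), region_ids)
  structure(list(region_ids = region_ids, nbrs = nbrs,
                 N = vapply(nbrs, length, integer(1))),
            class = "region_graph")
}

#' @export
print.region_graph <- function(x, ...) {
  cat("region_graph with", length(x$region_ids), "regions,",
      sum(x$N) / 2, "edges\n")
  invisible(x)
}

#' Read a region adjacency file
#'
#' Two dialects are accepted.  Edge list (canonical): first line the
#' number of regions S, then one `regionA regionB` pair per line;
#' single-token lines declare isolated regions.  BayesX-style `.gra`:
#' first line S, then for each region three lines -- label, neighbor
#' count, and 1-based neighbor positions.
#'
#' @param path path to the graph file; `.gra` extension selects the
#'   BayesX dialect.
#' @return a [region_graph()].
#' @export
read_adjacency <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  S <- suppressWarnings(as.integer(lines[1L]))
  if (is.na(S) || S < 1L) stop("first line must give the region count")
  body <- lines[-1L]
  if (grepl("\\.gra$", path, ignore.case = TRUE)) {
    if (length(body) != 3L * S) stop("malformed .gra file")
    labels <- body[seq(1L, by = 3L, length.out = S)]
    edges <- NULL
    for (i in seq_len(S)) {
      cnt <- as.integer(body[3L * i - 1L])
      idx <- if (cnt > 0L) as.integer(strsplit(body[3L * i], "\\s+")[[1L]])
             else integer(0)
      if (length(idx) != cnt) stop("neighbor count mismatch for region ",
                                   labels[i])
      if (cnt > 0L)
        edges <- rbind(edges, cbind(labels[i], labels[idx]))
    }
    g <- region_graph(labels, edges)
    # .gra listings must be symmetric
    for (s in labels) for (r in g$nbrs[[s]])
      if (!(s %in% g$nbrs[[r]])) stop("asymmetric adjacency: ", s, " ~ ", r)
    return(g)
  }
  toks <- strsplit(body, "\\s+")
  singles <- vapply(toks, length, integer(1)) == 1L
  regions <- unique(c(unlist(toks[singles]),
                      unlist(toks[!singles])))
  edges <- do.call(rbind, toks[!singles])
  if (!is.null(edges) && any(edges[, 1] == edges[, 2]))
    stop("self-loop in adjacency: ",
         edges[edges[, 1] == edges[, 2], 1][1])
  if (length(regions) != S)
    stop("file declares ", S, " regions but lists ", length(regions))
  region_graph(regions, edges)
}

#' The Kenya eight-province adjacency fixture
#'
#' Standard provincial contiguity of Kenya's eight former administrative
#' provinces (the regional units of the 1998-2014 survey rounds).  The
#' adjacency encodes
#' land-border contiguity and is shipped as a plain-text edge list.
#' @return a [region_graph()] with S = 8.
#' @export
kenya_region_graph <- function() {
  read_adjacency(system.file("extdata", "kenya_provinces.graph",
                             package = "geofgmc", mustWork = TRUE))
}

#' Intrinsic MRF (ICAR) precision structure
#'
#' Q = D - A with D = diag(neighbor counts) and A the binary adjacency
#' indicator.  Rows sum to zero; rank is S minus the number of
#' connected components.  Isolated regions trigger a warning (their
#' structured effect is fixed at zero downstream; heterogeneity is
#' absorbed by the unstructured term).
#'
#' @param graph a [region_graph()].
#' @return S x S matrix with region labels as dimnames.
#' @export
mrf_precision <- function(graph) {
  stopifnot(inherits(graph, "region_graph"))
  S <- length(graph$region_ids)
  if (S < 2L) stop("at least two regions required")
  if (any(graph$N == 0L))
    warning("isolated region(s): ",
            paste(graph$region_ids[graph$N == 0L], collapse = ", "),
            "; structured effect fixed at 0 there")
  Q <- -.adjacency_matrix(graph)
  diag(Q) <- graph$N
  Q
}

# binary adjacency indicator with region-label dimnames
.adjacency_matrix <- function(graph) {
  S <- length(graph$region_ids)
  A <- matrix(0, S, S, dimnames = list(graph$region_ids, graph$region_ids))
  for (s in graph$region_ids) A[s, graph$nbrs[[s]]] <- 1
  diag(A) <- 0
  A
}

# number of connected components (for the intrinsic rank)
.n_components <- function(graph) {
  S <- length(graph$region_ids)
  seen <- rep(FALSE, S)
  names(seen) <- graph$region_ids
  comps <- 0L
  for (s in graph$region_ids) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (seen[v]) next
      seen[v] <- TRUE
      queue <- c(queue, graph$nbrs[[v]][!seen[graph$nbrs[[v]]]])
    }
  }
  comps
}

#' ICAR full-conditional parameters for one region
#'
#' Under the intrinsic MRF prior, the structured effect of region `s`
#' given its neighbors is Gaussian with mean the neighbor average and
#' variance tau_s^2 / N_s.
#'
#' @param graph a [region_graph()].
#' @param s region label.
#' @param f named (or graph-ordered) vector of current structured
#'   effects.
#' @param tau_s scale parameter (tau_s > 0); the conditional variance is
#'   `tau_s^2 / N_s`.
#' @return list with `mean` and `variance`.
#' @export
conditional_prior_params <- function(graph, s, f, tau_s) {
  stopifnot(inherits(graph, "region_graph"))
  if (!(s %in% graph$region_ids)) stop("unknown region: ", s)
  if (tau_s <= 0) stop("tau_s must be positive")
  if (is.null(names(f))) names(f) <- graph$region_ids
  nb <- graph$nbrs[[s]]
  if (length(nb) == 0L) stop("isolated region has no conditional prior: ", s)
  list(mean = mean(f[nb]), variance = tau_s^2 / length(nb))
}

#' Moran's I with a permutation test
#'
#' I = (S/W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2
#' with binary (row-unstandardized) weights w_ij from the adjacency.
#' Inference is by random permutation of the region labels (robust at
#' small S); the p-value is two-sided.
#'
#' @param values numeric vector of length S (graph order or named).
#' @param graph a [region_graph()].
#' @param n_perm number of permutations, at least 99.
#' @param seed optional integer seed for the permutation stream.
#' @return list with `I`, `p_value`, `n_perm`.
#' @export
morans_i <- function(values, graph, n_perm = 999L, seed = NULL) {
  stopifnot(inherits(graph, "region_graph"))
  S <- length(graph$region_ids)
  if (length(values) != S) stop("values must have length S = ", S)
  if (!is.null(names(values))) values <- values[graph$region_ids]
  if (var(values) == 0) stop("values are constant; Moran's I undefined")
  if (n_perm < 99L) stop("n_perm must be at least 99")
  A <- .adjacency_matrix(graph)
  Wtot <- sum(A)
  stat <- function(x) {
    xc <- x - mean(x)
    (S / Wtot) * as.numeric(xc %*% A %*% xc) / sum(xc^2)
  }
  I <- stat(values)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
            globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  perm <- vapply(seq_len(n_perm), function(i) stat(sample(values)),
                 numeric(1))
  p_hi <- (1 + sum(perm >= I)) / (n_perm + 1)
  p_lo <- (1 + sum(perm <= I)) / (n_perm + 1)
  list(I = I, p_value = min(1, 2 * min(p_hi, p_lo)), n_perm = n_perm)
}
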