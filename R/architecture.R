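#' Network architecture: nodes, hierarchy and typed extrinsic edges
#'
#' A directed network over named cortical sources. Each node has a hierarchy
#' rank; edges are typed by the standard laminar rules — `feedforward` runs
#' from a lower- to a higher-rank node, `feedback` from higher to lower, and
#' `lateral` between homologous nodes of equal rank in opposite hemispheres.
#' A subset of edges (`b_mask`) may carry condition-specific log-scaling
#' modulation.
#'
#' @param nodes character vector of node labels.
#' @param rank integer hierarchy rank per node (same order as `nodes`).
#' @param edges data frame with columns `from`, `to`, `type`
#'   (feedforward/feedback/lateral).
#' @param b_mask logical vector marking which edges are modulated between
#'   conditions (default: all).
#' @return an object of class `network_architecture`.
#' @export
network_architecture <- function(nodes, rank, edges, b_mask = NULL) {
  stopifnot(length(nodes) == length(rank),
            all(c("from", "to", "type") %in% names(edges)))
  if (is.null(b_mask)) b_mask <- rep(TRUE, nrow(edges))
  stopifnot(length(b_mask) == nrow(edges))
  names(rank) <- nodes
  stopifnot(all(edges$from %in% nodes), all(edges$to %in% nodes),
            all(edges$type %in% c("feedforward", "feedback", "lateral")))
  # typed-edge consistency with the hierarchy
  rf <- rank[edges$from]; rt <- rank[edges$to]
  ok <- (edges$type == "feedforward" & rf < rt) |
    (edges$type == "feedback" & rf > rt) |
    (edges$type == "lateral" & rf == rt)
  if (!all(ok)) stop("edge types inconsistent with hierarchy ranks")
  structure(list(nodes = nodes, rank = rank,
                 edges = data.frame(edges, b_mask = b_mask)),
            class = "network_architecture")
}

#' @export
print.network_architecture <- function(x, ...) {
  cat(sprintf("network_architecture: %d nodes, %d edges (%s)\n",
              length(x$nodes), nrow(x$edges),
              paste(sprintf("%d %s", table(x$edges$type)[
                c("feedforward", "feedback", "lateral")],
                c("feedforward", "feedback", "lateral")), collapse = ", ")))
  invisible(x)
}

#' Default 7-node working-memory network
#'
#' Bilateral early visual cortex (EVC), intraparietal sulcus (IPS) and
#' middle frontal gyrus (MFG), plus a single midline superior frontal (SFG)
#' node. Within each hemispheric chain every lower-rank node projects
#' feedforward to every higher-rank node (the midline SFG participates in
#' both chains), every feedforward edge has a feedback reverse, and the
#' three homologous contra/ipsi pairs are laterally connected in both
#' directions: 12 feedforward, 12 feedback and 6 lateral edges. All 30 edges
#' are condition-modulated.
#'
#' @param sfg_rank hierarchy rank of the midline SFG node. The default (3)
#'   places SFG between IPS and MFG so that the MFG-to-SFG direction is a
#'   feedback connection; `sfg_rank = 5` is the alternative SFG-on-top
#'   ordering.
#' @return a [network_architecture()].
#' @export
build_default_network <- function(sfg_rank = 3) {
  stopifnot(sfg_rank %in% c(3, 5))
  nodes <- c("EVC_contra", "EVC_ipsi", "IPS_contra", "IPS_ipsi",
             "MFG_contra", "MFG_ipsi", "SFG")
  mfg_rank <- if (sfg_rank == 3) 4 else 4  # MFG rank fixed; SFG moves
  rank <- c(1, 1, 2, 2, mfg_rank, mfg_rank, sfg_rank)
  ff <- NULL
  for (h in c("contra", "ipsi")) {
    chain <- c(paste0("EVC_", h), paste0("IPS_", h), "SFG", paste0("MFG_", h))
    r <- rank[match(chain, nodes)]
    chain <- chain[order(r)]
    for (i in 1:(length(chain) - 1))
      for (j in (i + 1):length(chain))
        ff <- rbind(ff, data.frame(from = chain[i], to = chain[j],
                                   type = "feedforward"))
  }
  fb <- data.frame(from = ff$to, to = ff$from, type = "feedback")
  lat <- NULL
  for (pair in c("EVC", "IPS", "MFG")) {
    lat <- rbind(lat,
                 data.frame(from = paste0(pair, "_contra"),
                            to = paste0(pair, "_ipsi"), type = "lateral"),
                 data.frame(from = paste0(pair, "_ipsi"),
                            to = paste0(pair, "_contra"), type = "lateral"))
  }
  network_architecture(nodes, rank, rbind(ff, fb, lat))
}

#' Reduced n-node chain network
#'
#' A single hierarchy chain (ranks 1..n) with all-to-all feedforward edges up
#' the chain and their feedback reverses; no lateral edges. Used for fast
#' inversion and recovery experiments.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param nodes optional node labels.
#' @return a [network_architecture()].
#' @export
build_chain_network <- function(n_nodes = 3,
                                nodes = paste0("node", seq_len(n_nodes))) {
  stopifnot(n_nodes >= 2, length(nodes) == n_nodes)
  ff <- NULL
  for (i in 1:(n_nodes - 1)) for (j in (i + 1):n_nodes)
    ff <- rbind(ff, data.frame(from = nodes[i], to = nodes[j],
                               type = "feedforward"))
  fb <- data.frame(from = ff$to, to = ff$from, type = "feedback")
  network_architecture(nodes, seq_len(n_nodes), rbind(ff, fb))
}

#' Read / write a network architecture as JSON
#'
#' @param arch a [network_architecture()].
#' @param path file path.
#' @return `read_architecture` returns a [network_architecture()];
#'   `write_architecture` returns `path` invisibly.
#' @export
write_architecture <- function(arch, path) {
  jsonlite::write_json(
    list(nodes = arch$nodes, rank = unname(arch$rank),
         edges = arch$edges[c("from", "to", "type")],
         b_mask = arch$edges$b_mask),
    path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_architecture
#' @export
read_architecture <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  network_architecture(j$nodes, j$rank, j$edges, j$b_mask)
}

# number of edges
n_edges <- function(arch) nrow(arch$edges)

# edge label helper, e.g. "IPS_contra->SFG"
edge_labels <- function(arch) paste0(arch$edges$from, "->", arch$edges$to)
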