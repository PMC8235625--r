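#' Read and validate a rooted, bifurcating, time-calibrated tree
#'
#' Thin wrappers around \pkg{ape}'s Newick parser that enforce the contract
#' every downstream analysis assumes: the tree is rooted and fully
#' bifurcating, tip labels are unique, and all branch lengths are positive
#' (in millions of years). Polytomies are rejected rather than silently
#' resolved.
#'
#' @param path file path, or (for `validate_phylo`) a `phylo` object.
#' @return a validated `phylo` object.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("malformed Newick in ", path,
                                            ": ", conditionMessage(e),
                                            call. = FALSE))
  if (is.null(tree)) stop("malformed Newick in ", path, call. = FALSE)
  validate_phylo(tree)
}

#' @param tree a `phylo` object.
#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname read_newick
#' @export
validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a `phylo` object", call. = FALSE)
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  if (!ape::is.binary(tree))
    stop("tree contains polytomies; a fully bifurcating tree is required",
         call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels", call. = FALSE)
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0))
    stop("all branch lengths must be positive", call. = FALSE)
  tree
}

node_depths <- function(tree) ape::node.depth.edgelength(tree)

#' Graft species from a patch phylogeny onto a backbone with rescaling
#'
#' Adds taxa that are missing from the time-calibrated backbone using
#' divergence times from a second (patch) phylogeny whose absolute time
#' scale may differ. For each new taxon X the closest shared species S
#' (smallest patristic distance to X in the patch) anchors a scaling factor
#' obtained by cross multiplication, f = depth(S in backbone) / depth(S in
#' patch). X is then attached to S's lineage at f * t_div before present
#' (t_div = X-S divergence time in the patch) with pendant length f * t_div.
#' If the scaled divergence falls above an internal node of the backbone the
#' attachment simply moves to the corresponding ancestral edge; if it is
#' older than the backbone root the graft fails.
#'
#' @param backbone,patch `phylo` objects; the patch must contain each new
#'   taxon and at least one species shared with the backbone.
#' @param new_taxa character vector of patch tip labels to add.
#' @return the backbone with the new taxa attached (a valid `phylo`).
#' @export
graft_with_scaling <- function(backbone, patch, new_taxa) {
  backbone <- validate_phylo(backbone)
  patch <- validate_phylo(patch)
  for (x in new_taxa) {
    if (!(x %in% patch$tip.label))
      stop("taxon ", x, " not present in the patch tree", call. = FALSE)
    shared <- setdiff(intersect(patch$tip.label, backbone$tip.label),
                      new_taxa)
    if (!length(shared))
      stop("no shared species between backbone and patch", call. = FALSE)
    pd <- ape::cophenetic.phylo(patch)
    s <- shared[which.min(pd[x, shared])]
    dep_p <- node_depths(patch)
    dep_b <- node_depths(backbone)
    s_p <- match(s, patch$tip.label)
    s_b <- match(s, backbone$tip.label)
    f <- dep_b[s_b] / dep_p[s_p]
    mrca <- ape::getMRCA(patch, c(x, s))
    t_div <- dep_p[s_p] - dep_p[mrca]
    h <- f * t_div                      # attachment height before present
    if (h >= dep_b[s_b] - 1e-12)
      stop("divergence older than backbone constraint for taxon ", x,
           call. = FALSE)
    # walk rootward from S until the attachment height falls inside an edge
    target_depth <- dep_b[s_b] - h
    node <- s_b
    repeat {
      parent <- backbone$edge[backbone$edge[, 2L] == node, 1L]
      if (!length(parent))
        stop("divergence older than backbone constraint for taxon ", x,
             call. = FALSE)
      if (dep_b[parent] <= target_depth + 1e-12) break
      node <- parent
    }
    position <- dep_b[node] - target_depth
    backbone <- phytools::bind.tip(backbone, x, edge.length = h,
                                   where = node, position = position)
    backbone <- validate_phylo(backbone)
  }
  backbone
}

#' Replace a tip label, keeping the geometry untouched
#'
#' @param tree a `phylo`.
#' @param old_label,new_label tip labels.
#' @return the relabelled tree.
#' @export
substitute_tip <- function(tree, old_label, new_label) {
  i <- match(old_label, tree$tip.label)
  if (is.na(i)) stop("tip ", old_label, " not found", call. = FALSE)
  tree$tip.label[i] <- new_label
  tree
}

#' Maximum-parsimony ancestral-state reconstruction
#'
#' Unit-cost (Fitch) parsimony for a discrete character. For every internal
#' node the full most-parsimonious-reconstruction (MPR) state set is
#' computed exactly by dynamic programming with rerooting: `cost(v, s)` is
#' the minimum number of changes over the whole tree given node `v` fixed in
#' state `s`, and the node's states with minimal cost form its MPR set. The
#' returned probabilities are uniform over each node's MPR set, so an
#' unresolvable node (such as a root whose two subtrees demand different
#' states) gets 0.5/0.5.
#'
#' @param tree a `phylo`.
#' @param states named character/factor vector over all tips.
#' @return list with `node_probs` (internal nodes x states matrix, rows sum
#'   to 1; rownames are ape node numbers), `root_probs`, `score` (the
#'   parsimony score) and `states` (the state labels).
#' @export
asr_parsimony <- function(tree, states) {
  tree <- validate_phylo(tree)
  x <- as.character(states)[match(tree$tip.label, names(states))]
  if (anyNA(x)) stop("every tip needs a state", call. = FALSE)
  lev <- sort(unique(x))
  ns <- length(lev)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  big <- ntip + 1          # exceeds any attainable per-edge cost difference
  ord <- ape::reorder.phylo(tree, "postorder")
  E <- ord$edge
  # up-pass: up[v, s] = min changes within the subtree of v given v in s
  up <- matrix(0, ntip + nnode, ns)
  for (i in seq_len(ntip)) up[i, ] <- ifelse(lev == x[i], 0, big)
  for (e in seq_len(nrow(E))) {
    ch <- E[e, 2L]
    contrib <- pmin(up[ch, ], min(up[ch, ]) + 1)
    up[E[e, 1L], ] <- up[E[e, 1L], ] + contrib
  }
  root <- ntip + 1L
  # down-pass (rerooting): cost of everything outside v's subtree, given v
  down <- matrix(0, ntip + nnode, ns)
  children <- split(E[, 2L], E[, 1L])
  preorder <- rev(seq_len(nrow(E)))
  for (e in preorder) {
    p <- E[e, 1L]; ch <- E[e, 2L]
    sibs <- setdiff(children[[as.character(p)]], ch)
    rest <- down[p, ]
    for (sb in sibs) rest <- rest + pmin(up[sb, ], min(up[sb, ]) + 1)
    down[ch, ] <- vapply(seq_len(ns), function(s)
      min(rest + (seq_len(ns) != s)), 0)
  }
  total <- up + down
  score <- min(total[root, ])
  nodes <- root:(ntip + nnode)
  probs <- matrix(0, length(nodes), ns, dimnames = list(nodes, lev))
  for (i in seq_along(nodes)) {
    r <- total[nodes[i], ]
    best <- r <= min(r) + 1e-9
    probs[i, ] <- best / sum(best)
  }
  list(node_probs = probs, root_probs = probs[1L, ], score = score,
       states = lev)
}

#' Stochastic character mapping under the equal-rates model
#'
#' Fits the maximum-likelihood transition rate of the equal-rates 2-state
#' Markov model (via \pkg{phytools}' pruning-algorithm likelihood) and draws
#' `nsim` stochastic character histories conditional on the tip data, with a
#' flat root prior. Per-node posterior state frequencies are returned with
#' Monte Carlo standard errors. If the tips show no variation the invariant
#' state is returned with probability 1 (the fitted rate is 0).
#'
#' @param tree a `phylo`.
#' @param states named character/factor over tips.
#' @param nsim number of sampled histories.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return list with `node_posterior` (internal nodes x states), `mc_se`,
#'   `Q` (fitted rate matrix), `n_changes` (mean number of state changes per
#'   map) and `maps` (the `multiSimmap` object, or `NULL` for invariant
#'   data).
#' @export
simmap_er <- function(tree, states, nsim = 1000L, seed = 1L) {
  tree <- validate_phylo(tree)
  x <- as.character(states)[match(tree$tip.label, names(states))]
  if (anyNA(x)) stop("every tip needs a state", call. = FALSE)
  names(x) <- tree$tip.label
  lev <- sort(unique(x))
  ntip <- length(tree$tip.label)
  nodes <- as.character((ntip + 1L):(ntip + tree$Nnode))
  if (length(lev) == 1L) {
    post <- matrix(1, tree$Nnode, 1L, dimnames = list(nodes, lev))
    return(list(node_posterior = post,
                mc_se = post * 0, Q = matrix(0, 1, 1,
                  dimnames = list(lev, lev)),
                n_changes = 0, maps = NULL))
  }
  set.seed(seed)
  maps <- phytools::make.simmap(tree, x, model = "ER", nsim = nsim,
                                pi = "equal", Q = "empirical",
                                message = FALSE)
  sm <- summary(maps)
  post <- sm$ace[nodes, , drop = FALSE]
  list(node_posterior = post,
       mc_se = sqrt(post * (1 - post) / nsim),
       Q = maps[[1L]]$Q,
       n_changes = mean(sm$count[, "N"]),
       maps = maps)
}

#' Study phylogeny and locomotor categories (approximate fixture)
#'
#' A 25-species composite callitrichid phylogeny matching the published
#' clade structure (the *Leontocebus* clade; a *Saguinus* clade containing
#' the *midas* and *geoffroyi/oedipus* groups; *Leontopithecus* sister to
#' *Callimico* plus the marmosets, with *Cebuella* inside the
#' *Mico*/*Callithrix* region), together with each species' locomotor
#' category (VCL = vertical clinging and leaping, HL = horizontal leaping).
#' Branch lengths are APPROXIMATE (plausible divergence times in My): only
#' topology-dependent analyses (e.g. parsimony ancestral states) should
#' assert against this fixture.
#'
#' @return `callitrichid_tree()`: a `phylo`; `callitrichid_locomotion()`: a
#'   named character vector of categories over the same 25 species.
#' @export
callitrichid_tree <- function() {
  path <- system.file("extdata", "callitrichid_tree_approx.nwk",
                      package = "morphorate", mustWork = TRUE)
  read_newick(path)
}

#' @rdname callitrichid_tree
#' @export
callitrichid_locomotion <- function() {
  path <- system.file("extdata", "callitrichid_locomotion.csv",
                      package = "morphorate", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$category, df$species_id)
}

#' Build a composite phylogeny from a YAML description
#'
#' Reads a small YAML config describing a composite-tree build — the
#' backbone Newick file, one or more patch trees each with the taxa to add
#' from it, and optional tip-label substitutions — and executes it with
#' [graft_with_scaling] and [substitute_tip]. Paths are resolved relative
#' to the config file. Expected keys:
#'
#' ```yaml
#' backbone: backbone.nwk
#' patches:
#'   - tree: patch1.nwk
#'     add: [Taxon_x, Taxon_y]
#' substitutions:
#'   - {old: Taxon_a, new: Taxon_b}
#' ```
#'
#' @param path YAML file.
#' @return the composite `phylo`.
#' @export
build_composite_tree <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$backbone)) stop("config needs a `backbone`", call. = FALSE)
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  tree <- read_newick(resolve(cfg$backbone))
  for (patch in cfg$patches) {
    ptree <- read_newick(resolve(patch$tree))
    tree <- graft_with_scaling(tree, ptree, unlist(patch$add))
  }
  for (sub in cfg$substitutions)
    tree <- substitute_tip(tree, sub$old, sub$new)
  tree
}
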