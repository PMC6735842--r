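# Phylogeny construction, dating and covariance extraction.
#
# Trees are ape "phylo" objects throughout. Because no resolved,
# dated megatree for the study flora can be redistributed, the package
# builds a polytomous stand-in from the trait table's order/family/genus
# columns and dates it by even interpolation between user-supplied node
# ages (the BLADJ procedure). The packaged age table
# (`node_ages_synthetic.csv`) is a synthetic stand-in with plausible
# crown-age values; users can substitute their own calibration.

#' Build a taxonomy-backbone phylogeny from a trait table
#'
#' Creates a rooted tree with one polytomy of orders at the root, families
#' nested within orders, genus nodes wherever two or more congeners occur,
#' and species as tips. Internal nodes are labelled with the taxon name so
#' that an age table can be attached later; all branch lengths are set to 1
#' pending dating. Below the genus level the topology is unresolved by
#' construction.
#'
#' @param df A `trait_table` data.frame with `species`, `family`, `order`.
#' @return An ape `phylo` object (may contain single-child nodes for
#'   monotypic orders/families; [phylo_covariance()] collapses these).
#' @export
build_taxonomy_tree <- function(df) {
  validate_trait_table(df)
  tips <- gsub(" ", "_", df$species)
  if (nrow(df) == 1L) {
    # ape cannot parse a one-tip nested newick; build the phylo directly
    return(structure(list(edge = matrix(c(2L, 1L), 1, 2),
                          tip.label = tips, Nnode = 1L,
                          node.label = "Root", edge.length = 1),
                     class = "phylo", order = "cladewise"))
  }
  genus <- vapply(strsplit(df$species, " "), `[`, "", 1L)
  genus_nwk <- function(idx) {
    g <- genus[idx][1]
    if (length(idx) == 1L) tips[idx]
    else sprintf("(%s)%s", paste(tips[idx], collapse = ","), g)
  }
  fam_nwk <- function(idx) {
    fam <- df$family[idx][1]
    parts <- vapply(split(idx, genus[idx]), genus_nwk, "")
    sprintf("(%s)%s", paste(parts, collapse = ","), fam)
  }
  ord_nwk <- function(idx) {
    parts <- vapply(split(idx, df$family[idx]), fam_nwk, "")
    sprintf("(%s)%s", paste(parts, collapse = ","), df$order[idx][1])
  }
  parts <- vapply(split(seq_len(nrow(df)), df$order), ord_nwk, "")
  nwk <- sprintf("(%s)Root;", paste(parts, collapse = ","))
  tree <- ape::read.tree(text = nwk)
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree
}

node_ages_from_table <- function(tree, ages) {
  n_tip <- ape::Ntip(tree)
  n_node <- tree$Nnode
  age <- rep(NA_real_, n_tip + n_node)
  age[seq_len(n_tip)] <- 0
  labs <- tree$node.label %||% rep("", n_node)
  hit <- match(labs, names(ages))
  age[n_tip + which(!is.na(hit))] <- ages[hit[!is.na(hit)]]
  age
}

#' Date a tree by even interpolation between known node ages (BLADJ)
#'
#' Nodes named in the age table take their given age (Myr); tips are age
#' 0. Each remaining node is placed by linear interpolation along the
#' path between its nearest dated ancestor and its nearest dated
#' descendant (fewest intervening edges; age ties broken towards the
#' older age), processed root-to-tip so that already-placed nodes
#' constrain their descendants. Branch lengths are then parent age minus
#' child age, so the result is ultrametric with depth equal to the root
#' age.
#'
#' @param tree A `phylo` with labelled internal nodes (e.g. from
#'   [build_taxonomy_tree()]).
#' @param ages Named numeric vector of ages in Myr (see
#'   [load_node_ages()]). Must date the root.
#' @return The dated, ultrametric `phylo`.
#' @export
bladj_adjust <- function(tree, ages) {
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  root <- n_tip + 1L
  age <- node_ages_from_table(tree, ages)
  if (is.na(age[root])) {
    stop_seedspan("the root must have an age in the age table",
                  "seedspan_invalid_input")
  }
  parent <- integer(n_all)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  children <- split(tree$edge[, 2], tree$edge[, 1])
  node_name <- function(v) {
    if (v <= n_tip) tree$tip.label[v]
    else (tree$node.label %||% rep("", tree$Nnode))[v - n_tip]
  }

  # check dated-pair monotonicity before interpolating
  for (v in seq_len(n_all)) {
    if (v == root || is.na(age[v])) next
    u <- parent[v]
    while (u != 0L && is.na(age[u])) u <- parent[u]
    if (u != 0L && age[v] >= age[u] && !(age[v] == 0 && age[u] == 0)) {
      stop_seedspan(sprintf(
        "age inversion: '%s' (%.3g Myr) is not younger than its dated ancestor '%s' (%.3g Myr)",
        node_name(v), age[v], node_name(u), age[u]),
        "seedspan_invalid_input")
    }
  }

  # preorder over internal nodes (root first)
  ord <- root
  queue <- root
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    kids <- children[[as.character(v)]]
    kids <- kids[kids > n_tip]
    ord <- c(ord, kids)
    queue <- c(queue, kids)
  }
  for (v in ord) {
    if (!is.na(age[v])) next
    # nearest dated ancestor (guaranteed: root is dated, ancestors
    # precede v in preorder so interpolated ones count as dated)
    u <- parent[v]; d_anc <- 1L
    while (is.na(age[u])) { u <- parent[u]; d_anc <- d_anc + 1L }
    # nearest dated descendant by BFS; ties -> oldest age
    d_desc <- NA_integer_; a_desc <- NA_real_
    frontier <- children[[as.character(v)]]
    depth <- 1L
    while (is.na(d_desc) && length(frontier)) {
      dated <- frontier[!is.na(age[frontier])]
      if (length(dated)) {
        d_desc <- depth
        a_desc <- max(age[dated])
      } else {
        frontier <- unlist(children[as.character(frontier)], use.names = FALSE)
        depth <- depth + 1L
      }
    }
    age[v] <- age[u] - (age[u] - a_desc) * d_anc / (d_anc + d_desc)
  }
  tree$edge.length <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
  if (any(tree$edge.length < -1e-9)) {
    stop_seedspan("internal error: negative branch length after dating",
                  "seedspan_fit_error")
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Read a node-age table
#'
#' CSV with columns `taxon, age_myr`; ages must be non-negative.
#'
#' @param path CSV path; default is the packaged synthetic age table (a
#'   stand-in with plausible but uncalibrated crown ages).
#' @return Named numeric vector of ages.
#' @export
load_node_ages <- function(path = seedspan_example("node_ages_synthetic.csv")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "age_myr") %in% names(df))) {
    stop_seedspan("age table needs columns taxon, age_myr",
                  "seedspan_schema_error")
  }
  if (any(!is.finite(df$age_myr) | df$age_myr < 0)) {
    stop_seedspan("ages must be finite and >= 0", "seedspan_schema_error")
  }
  stats::setNames(df$age_myr, df$taxon)
}

#' Phylogenetic covariance matrix of a dated tree
#'
#' V\[i, j\] is the shared root-to-MRCA path length of tips i and j (Myr);
#' the diagonal is each tip's root-to-tip depth. Single-child nodes are
#' collapsed first. Zero-length terminal branches (same-age congeners)
#' are perturbed by 1e-6 Myr with a warning so V stays invertible.
#'
#' @param tree A dated `phylo`.
#' @return A symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
phylo_covariance <- function(tree) {
  if (is.null(tree$edge.length)) {
    stop_seedspan("tree has no branch lengths; date it first",
                  "seedspan_invalid_input")
  }
  if (any(tree$edge.length < 0)) {
    stop_seedspan("negative branch length in tree", "seedspan_invalid_input")
  }
  tree <- ape::collapse.singles(tree)
  term <- tree$edge[, 2] <= ape::Ntip(tree)
  if (any(tree$edge.length[term] == 0)) {
    warning("zero-length terminal branch(es) perturbed by 1e-6 Myr",
            call. = FALSE)
    tree$edge.length[term & tree$edge.length == 0] <- 1e-6
  }
  ape::vcv.phylo(tree)
}

#' Pagel lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries by `lambda` while keeping the
#' diagonal: `lambda = 1` leaves the matrix unchanged, `lambda = 0` gives
#' the star phylogeny (no phylogenetic signal).
#'
#' @param V Covariance matrix from [phylo_covariance()].
#' @param lambda Number in \[0, 1\].
#' @return The transformed matrix.
#' @export
lambda_transform <- function(V, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1) {
    stop_seedspan("lambda must be a single number in [0, 1]",
                  "seedspan_invalid_input")
  }
  W <- V * lambda
  diag(W) <- diag(V)
  W
}

#' Read / write Newick trees
#'
#' Thin wrappers around ape's Newick parser and writer that turn malformed
#' input into a structured error. Round trips preserve topology, labels
#' and branch lengths to at least 6 decimals.
#'
#' @param path File path.
#' @return `read_newick`: a `phylo`; `write_newick`: the path, invisibly.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) {
    stop_seedspan(sprintf("file not found: %s", path), "seedspan_io_error")
  }
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close) {
    stop_seedspan(sprintf(
      "malformed Newick in %s: %d '(' vs %d ')'", path, n_open, n_close),
      "seedspan_parse_error")
  }
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) {
    stop_seedspan(sprintf("failed to parse Newick file %s", path),
                  "seedspan_parse_error")
  }
  tree
}

#' @param tree A `phylo` object.
#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
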