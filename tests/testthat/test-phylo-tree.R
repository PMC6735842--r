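test_that("taxonomy tree groups congeners, families and orders", {
  tt <- fixture_table()
  tree <- build_taxonomy_tree(tt)
  expect_equal(ape::Ntip(tree), 39L)
  mrca <- ape::getMRCA(tree, c("Trifolium_arvense", "Trifolium_montanum"))
  clade <- ape::extract.clade(tree, mrca)
  expect_setequal(clade$tip.label,
                  c("Trifolium_arvense", "Trifolium_montanum"))
  # the Trifolium pair sits inside Fabaceae inside Fabales
  fab <- ape::extract.clade(
    tree, ape::Ntip(tree) + which(tree$node.label == "Fabaceae"))
  expect_setequal(fab$tip.label,
                  gsub(" ", "_", tt$species[tt$family == "Fabaceae"]))
  ord <- ape::extract.clade(
    tree, ape::Ntip(tree) + which(tree$node.label == "Fabales"))
  expect_setequal(ord$tip.label, fab$tip.label)
})

test_that("degenerate taxonomies build valid trees", {
  two <- data.frame(species = c("Aus bus", "Cus dus"),
                    family = c("Aaceae", "Baceae"),
                    order = c("Aales", "Bales"),
                    endosperm = "N", dormancy = "ND", p50 = 1, p50_se = 0,
                    stringsAsFactors = FALSE)
  tr <- ape::collapse.singles(build_taxonomy_tree(two))
  expect_equal(ape::Ntip(tr), 2L)
  expect_equal(tr$Nnode, 1L)  # joined at the root
  one <- build_taxonomy_tree(two[1, ])
  expect_equal(ape::Ntip(one), 1L)
  expect_equal(one$tip.label, "Aus_bus")
})

test_that("BLADJ interpolation matches the hand-worked chains", {
  # one undated node between root (100) and a tip
  tr <- ape::read.tree(text = "((A:1)U:1,B:1)Root;")
  d <- bladj_adjust(tr, c(Root = 100))
  depths <- ape::node.depth.edgelength(d)
  expect_equal(max(depths), 100)
  u_age <- 100 - ape::node.depth.edgelength(d)[ape::Ntip(d) +
                                                 which(d$node.label == "U")]
  expect_equal(u_age, 50)

  # two undated nodes in series: ages 66.67 and 33.33
  tr2 <- ape::read.tree(text = "(((A:1)U2:1)U1:1,B:1)Root;")
  d2 <- bladj_adjust(tr2, c(Root = 100))
  ages2 <- 100 - ape::node.depth.edgelength(d2)
  expect_equal(ages2[ape::Ntip(d2) + which(d2$node.label == "U1")],
               200 / 3, tolerance = 1e-9)
  expect_equal(ages2[ape::Ntip(d2) + which(d2$node.label == "U2")],
               100 / 3, tolerance = 1e-9)

  # undated node between the root (100) and an interior dated node (40)
  tr3 <- ape::read.tree(text = "(((A:1)M:1)U:1,B:1)Root;")
  d3 <- bladj_adjust(tr3, c(Root = 100, M = 40))
  ages3 <- 100 - ape::node.depth.edgelength(d3)
  expect_equal(ages3[ape::Ntip(d3) + which(d3$node.label == "U")], 70)

  # age inversion is an error naming both taxa
  expect_error(bladj_adjust(tr3, c(Root = 100, M = 150)),
               "M.*Root|Root.*M", class = "seedspan_invalid_input")
})

test_that("dating the packaged taxonomy gives an ultrametric tree", {
  dtree <- fixture_tree()
  expect_true(ape::is.ultrametric(dtree, tol = 1e-9))
  expect_equal(max(ape::node.depth.edgelength(dtree)),
               unname(load_node_ages()[["Root"]]))
  expect_true(all(dtree$edge.length >= 0))
})

test_that("phylogenetic covariance equals shared path lengths", {
  V2 <- phylo_covariance(ape::read.tree(text = "(A:100,B:100);"))
  expect_equal(unname(V2), diag(c(100, 100)))
  V3 <- phylo_covariance(tree3())
  expect_equal(V3["A", "B"], 75)
  expect_equal(V3["A", "A"], 100)
  expect_equal(V3["A", "C"], 0)
  star <- gen_tree(6, "star", root_age = 42)
  expect_equal(unname(phylo_covariance(star)), 42 * diag(6))
  # naive path-length oracle agrees on the dated fixture tree
  dtree <- ape::collapse.singles(fixture_tree())
  dtree$edge.length[dtree$edge[, 2] <= ape::Ntip(dtree) &
                      dtree$edge.length == 0] <- 1e-6
  V <- phylo_covariance(dtree)
  expect_equal(V, vcv_oracle(dtree)[rownames(V), colnames(V)],
               tolerance = 1e-9)
})

test_that("covariance matrices stay PSD with constant diagonal", {
  dtree <- fixture_tree()
  V <- suppressWarnings(phylo_covariance(dtree))
  expect_lt(max(abs(diag(V) - max(diag(V)))), 1e-5)
  for (lam in c(0, 0.3, 0.7, 1)) {
    ev <- eigen(lambda_transform(V, lam), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(ev))
  }
})

test_that("lambda transform scales only the off-diagonal", {
  V <- phylo_covariance(tree3())
  expect_equal(lambda_transform(V, 1), V)
  expect_equal(lambda_transform(V, 0), diag(diag(V)), ignore_attr = TRUE)
  expect_equal(lambda_transform(V, 0.5)["A", "B"], 37.5)
  expect_equal(diag(lambda_transform(V, 0.5)), diag(V))
  expect_error(lambda_transform(V, 1.2), class = "seedspan_invalid_input")
})

test_that("newick I/O round-trips and rejects malformed input", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(unname(diag(phylo_covariance(tr))), c(2, 2, 2))

  dtree <- fixture_tree()
  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_newick(dtree, tmp)
  back <- read_newick(tmp)
  expect_equal(sort(back$tip.label), sort(dtree$tip.label))
  expect_true(ape::all.equal.phylo(back, dtree, use.edge.length = FALSE))
  Vb <- suppressWarnings(phylo_covariance(back))
  Va <- suppressWarnings(phylo_covariance(dtree))
  expect_equal(Vb[rownames(Va), colnames(Va)], Va, tolerance = 1e-6)

  bad <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2;", bad)
  expect_error(read_newick(bad), class = "seedspan_parse_error")
})

test_that("zero-length terminal branches are perturbed with a warning", {
  tr <- ape::read.tree(text = "((A:0,B:0):100,C:100);")
  expect_warning(V <- phylo_covariance(tr), "perturbed")
  expect_gt(det(V), 0)
})
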