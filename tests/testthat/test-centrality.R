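test_that("adjacency aggregation sums per mechanism and handles negatives", {
  rows <- list(
    edge_row(source = "A", target = "B", ligand = "L1", receptor = "R1",
             ligand_scaled = 1, receptor_scaled = 1),
    edge_row(source = "A", target = "B", ligand = "L2", receptor = "R2",
             ligand_scaled = 1, receptor_scaled = 1),
    edge_row(source = "B", target = "A", ligand = "L3", receptor = "R3",
             ligand_scaled = -0.5, receptor_scaled = -0.5),
    edge_row(source = "A", target = "A", ligand = "L4", receptor = "R4",
             ligand_scaled = 3, receptor_scaled = 3))
  conn <- toy_connectome(rows)
  adj <- aggregate_adjacency(conn, "weight_scale")
  expect_equal(adj["A", "B"], 2)    # two mechanisms of weight 1 summed
  expect_equal(adj["B", "A"], 0)    # negative floored at 0
  expect_equal(adj["A", "A"], 3)    # self-edge on the diagonal
  adj_shift <- aggregate_adjacency(conn, "weight_scale", negative = "shift")
  expect_equal(min(adj_shift["B", "A"]), 0)
  expect_equal(adj_shift["A", "B"], 2 * 1.5)
  neg_only <- toy_connectome(list(edge_row(ligand_scaled = -1, receptor_scaled = -1)))
  expect_error(aggregate_adjacency(neg_only, "weight_scale"), "no positive-weight")
})

test_that("HITS closed forms are exact", {
  adj <- matrix(c(0, 0, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  # A sends to B only
  h <- suppressWarnings(hits_centrality(adj))
  expect_equal(unname(h$hub), c(1, 0))
  expect_equal(unname(h$authority), c(0, 1))
  sym <- matrix(c(0, 1, 1, 0), 2, 2)
  h2 <- hits_centrality(sym)
  expect_equal(unname(h2$hub), c(1, 1))
  expect_equal(unname(h2$authority), c(1, 1))
  # A -> B (weight 2) and A -> C (weight 1): authority direction (0, 2, 1)
  adj3 <- rbind(c(0, 2, 1), c(0, 0, 0), c(0, 0, 0))
  h3 <- suppressWarnings(hits_centrality(adj3))
  expect_equal(unname(h3$authority), c(0, 1, 0.5), tolerance = 1e-10)
  expect_equal(unname(h3$hub), c(1, 0, 0), tolerance = 1e-10)
})

test_that("power iteration matches a dense eigendecomposition", {
  set.seed(77)
  for (i in 1:30) {
    n <- sample(2:10, 1)
    adj <- matrix(runif(n * n), n, n) * matrix(rbinom(n * n, 1, 0.7), n, n)
    if (all(adj == 0)) next
    h <- suppressWarnings(hits_centrality(adj, tol = 1e-13, max_iter = 10000))
    ev_hub <- eigen(adj %*% t(adj), symmetric = TRUE)$vectors[, 1]
    ev_auth <- eigen(t(adj) %*% adj, symmetric = TRUE)$vectors[, 1]
    orient <- function(v) { v <- v * sign(sum(v)); abs(v) / max(abs(v)) }
    expect_equal(unname(h$hub), orient(ev_hub), tolerance = 1e-8)
    expect_equal(unname(h$authority), orient(ev_auth), tolerance = 1e-8)
  }
})

test_that("hub/authority scores are invariant to global rescaling", {
  set.seed(13)
  adj <- matrix(runif(25), 5, 5)
  h1 <- hits_centrality(adj)
  h2 <- hits_centrality(adj * 37.5)
  expect_equal(h1$hub, h2$hub, tolerance = 1e-9)
  expect_equal(h1$authority, h2$authority, tolerance = 1e-9)
})

test_that("HITS contracts: invalid input and disconnected components", {
  expect_error(hits_centrality(matrix(0, 2, 2)), "no positive")
  expect_error(hits_centrality(matrix(c(0, -1, 0, 0), 2, 2)), "non-negative")
  two_comp <- rbind(c(0, 1, 0, 0), c(0, 0, 0, 0),
                    c(0, 0, 0, 1), c(0, 0, 0, 0))
  expect_warning(hits_centrality(two_comp), "component")
})

test_that("edgeweight fractions are normalized flows", {
  adj <- matrix(c(0, 3, 1, 0), 2, 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("A", "B")))
  wf <- weight_fractions(adj)
  expect_equal(unname(wf$out_frac), c(0.75, 0.25))
  expect_equal(unname(wf$in_frac), c(0.25, 0.75))
  expect_equal(sum(wf$out_frac), 1)
  expect_equal(sum(wf$in_frac), 1)
  # uniform complete graph without self-edges
  u <- matrix(1, 3, 3) - diag(3)
  wfu <- weight_fractions(u)
  expect_equal(unname(wfu$out_frac), rep(1 / 3, 3))
  expect_equal(unname(wfu$in_frac), rep(1 / 3, 3))
  expect_error(weight_fractions(matrix(0, 2, 2)), "zero")
})

test_that("per-family centrality builds one block per family and skips dead ones", {
  rows <- list(
    edge_row(source = "A", target = "B", ligand = "L1", receptor = "R1",
             family = "F1", ligand_scaled = 1, receptor_scaled = 1),
    edge_row(source = "A", target = "B", ligand = "L2", receptor = "R2",
             family = "F2", ligand_scaled = 2, receptor_scaled = 2),
    edge_row(source = "B", target = "A", ligand = "L3", receptor = "R3",
             family = "DEAD", ligand_scaled = -1, receptor_scaled = -1))
  conn <- toy_connectome(rows)
  tab <- suppressWarnings(suppressMessages(family_centrality(conn, "weight_scale")))
  expect_setequal(unique(tab$network_label), c("F1", "F2"))
  for (fam in c("F1", "F2")) {
    block <- tab[tab$network_label == fam, ]
    expect_equal(block$hub_score[block$cluster == "A"], 1)
    expect_equal(block$authority_score[block$cluster == "B"], 1)
    expect_equal(sum(block$out_weight_frac), 1, tolerance = 1e-9)
    expect_equal(sum(block$in_weight_frac), 1, tolerance = 1e-9)
  }
})

test_that("dominant-receiver grouping follows the documented tie-breaks", {
  tab <- data.frame(
    network_label = c("F1", "F1", "F2", "F2", "F3", "F3"),
    cluster = c("endo", "mes", "endo", "mes", "ccc", "aaa"),
    hub_score = 1, authority_score = c(1, 0.4, 0.8, 0.8, 0.5, 0.5),
    out_weight_frac = 0.5, in_weight_frac = c(0.5, 0.5, 0.2, 0.7, 0.5, 0.5),
    n_edges_considered = 4L)
  class(tab) <- c("centrality_table", "data.frame")
  cm <- c(endo = "Endo", mes = "Mes", aaa = "ClassA", ccc = "ClassC")
  grouped <- group_by_dominant_receiver(tab, cm)
  expect_equal(grouped[["F1"]], "Endo")            # plain argmax authority
  expect_equal(grouped[["F2"]], "Mes")             # authority tie -> in_weight_frac
  expect_equal(grouped[["F3"]], "ClassA")          # full tie -> lexicographic
  expect_error(group_by_dominant_receiver(tab, cm[-1]), "endo")
})

test_that("centrality comparison stacks systems without aligning node sets", {
  t1 <- data.frame(network_label = "F1", cluster = c("A", "B"),
                   hub_score = c(1, 0), authority_score = c(0, 1),
                   out_weight_frac = c(1, 0), in_weight_frac = c(0, 1),
                   n_edges_considered = 2L)
  t2 <- t1; t2$cluster <- c("X", "Y")
  out <- compare_centrality(list(day0 = t1, day7 = t2))
  expect_equal(nrow(out), 4)
  expect_setequal(out$cluster, c("A", "B", "X", "Y"))
  same <- compare_centrality(list(s1 = t1, s2 = t1))
  expect_equal(same$hub_score[same$system == "s1"],
               same$hub_score[same$system == "s2"])
  expect_warning(expect_warning(
    compare_centrality(list(a = t1, b = t2), network = "F9")), "no rows")
  expect_error(compare_centrality(list(t1)), "named")
})
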