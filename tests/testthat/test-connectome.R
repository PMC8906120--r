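three_cluster_profile <- function() {
  cl <- c("alpha", "beta", "delta")
  genes <- c("L1", "L2", "R1", "R2")
  mean_norm <- matrix(c(2, 0.5, 1, 1, 1, 1, 3, 1, 0.2, 1, 1, 1),
                      nrow = 3, dimnames = list(cl, genes))
  manual_profile(mean_norm,
                 mean_scaled = mean_norm - 1,
                 frac_expr = matrix(0.6, 3, 4, dimnames = list(cl, genes)),
                 pval = matrix(0.01, 3, 4, dimnames = list(cl, genes)))
}

two_mech_db <- function() lr_database(c("L1", "L2"), c("R1", "R2"),
                                      family = c("F1", "F2"))

test_that("the full edge list enumerates every source-target-mechanism triple", {
  conn <- create_connectome(three_cluster_profile(), two_mech_db())
  expect_equal(nrow(conn), 3 * 3 * 2)
  expect_equal(anyDuplicated(paste(conn$source, conn$target, conn$mechanism_id)), 0)
  # deterministic order: mechanism, then source, then target
  expect_equal(conn$mechanism_id, rep(c("L1|R1", "L2|R2"), each = 9))
  expect_equal(conn$source[1:9], rep(c("alpha", "beta", "delta"), each = 3))
  # self-edges present; drop flag removes them
  expect_equal(sum(conn$source == conn$target), 6)
  conn_ns <- create_connectome(three_cluster_profile(), two_mech_db(),
                               drop_self_edges = TRUE)
  expect_equal(nrow(conn_ns), 12)
})

test_that("edgeweights follow their defining formulas on every edge", {
  conn <- create_connectome(three_cluster_profile(), two_mech_db())
  expect_equal(conn$weight_norm, conn$ligand_norm * conn$receptor_norm)
  expect_equal(conn$weight_scale, (conn$ligand_scaled + conn$receptor_scaled) / 2)
  e <- conn[conn$source == "alpha" & conn$target == "beta" &
              conn$mechanism_id == "L1|R1", ]
  expect_equal(e$ligand_norm, 2)    # alpha's L1
  expect_equal(e$receptor_norm, 1)  # beta's R1
  expect_equal(e$weight_norm, 2)
})

test_that("database restriction happens inside create_connectome", {
  prof <- three_cluster_profile()
  db <- lr_database(c("L1", "L9"), c("R1", "R9"))
  conn <- suppressMessages(create_connectome(prof, db))
  expect_equal(length(attr(conn, "mechanisms")), 1)
  db_bad <- lr_database("L9", "R9")
  expect_error(suppressWarnings(suppressMessages(create_connectome(prof, db_bad))),
               "no ligand-receptor mechanism")
})

test_that("fraction and p-value gates use strict inequalities", {
  rows <- list(
    edge_row(ligand = "L1", receptor = "R1", ligand_frac = 0.10),        # frac == threshold: drop
    edge_row(ligand = "L2", receptor = "R2", ligand_p = 0.05),           # p == threshold: drop
    edge_row(ligand = "L3", receptor = "R3"),                            # keep
    edge_row(ligand = "L4", receptor = "R4", receptor_frac = 0.05))      # drop
  conn <- toy_connectome(rows)
  out <- filter_connectome(conn, min_frac = 0.1, max_p = 0.05)
  expect_equal(out$mechanism_id, "L3|R3")
})

test_that("the four-edge conjunction example keeps exactly one edge", {
  rows <- list(
    edge_row(source = "A", ligand = "L1", receptor = "R1",
             ligand_frac = 0.5, receptor_frac = 0.5),
    edge_row(source = "B", ligand = "L1", receptor = "R1",
             ligand_frac = 0.05, receptor_frac = 0.5),
    edge_row(source = "C", ligand = "L1", receptor = "R1",
             ligand_frac = 0.5, receptor_frac = 0.05),
    edge_row(source = "D", ligand = "L1", receptor = "R1",
             ligand_frac = 0.5, receptor_frac = 0.5, ligand_p = 0.5))
  out <- filter_connectome(toy_connectome(rows), min_frac = 0.1, max_p = 0.05)
  expect_equal(nrow(out), 1)
  expect_equal(out$source, "A")
})

test_that("the z-score gate requires both genes above the threshold", {
  rows <- list(
    edge_row(ligand = "L1", receptor = "R1", ligand_scaled = 1.5, receptor_scaled = 1.5),
    edge_row(ligand = "L2", receptor = "R2", ligand_scaled = 1.5, receptor_scaled = 0.5),
    edge_row(ligand = "L3", receptor = "R3", ligand_scaled = 1.0, receptor_scaled = 1.5))
  out <- filter_connectome(toy_connectome(rows), min_frac = 0, max_p = 1, min_z = 1)
  expect_equal(out$mechanism_id, "L1|R1")  # == 1 drops (strict)
})

test_that("filtering is monotone in its thresholds and idempotent", {
  conn <- random_connectome(5, 6, seed = 3)
  loose <- filter_connectome(conn, min_frac = 0.1, max_p = 0.5)
  tight <- suppressMessages(filter_connectome(conn, min_frac = 0.3, max_p = 0.1))
  expect_true(all(paste(tight$source, tight$target, tight$mechanism_id) %in%
                    paste(loose$source, loose$target, loose$mechanism_id)))
  again <- filter_connectome(loose, min_frac = 0.1, max_p = 0.5)
  expect_equal(edges_df(again), edges_df(loose))
  expect_error(filter_connectome(conn, min_frac = 1.5), "min_frac")
  expect_error(filter_connectome(conn, max_p = 0), "max_p")
})

test_that("slices select the canonical sub-networks", {
  conn <- create_connectome(three_cluster_profile(), two_mech_db())
  expect_equal(nrow(slice_connectome(conn, "niche", "beta")), 6)   # 3 sources x 2 mech
  expect_equal(nrow(slice_connectome(conn, "outgoing", "alpha")), 6)
  expect_equal(nrow(slice_connectome(conn, "interactome", "L1|R1")), 9)
  vec <- slice_connectome(conn, "vector", c("alpha", "alpha"))
  expect_equal(nrow(vec), 2)  # self-signaling included
  expect_error(slice_connectome(conn, "interactome", "NOPE|X"), "valid")
  expect_error(slice_connectome(conn, "niche", "gamma"), "valid")
})

test_that("a vector slice equals outgoing composed with niche", {
  conn <- random_connectome(4, 3, seed = 9)
  direct <- slice_connectome(conn, "vector", c("K2", "K3"))
  composed <- slice_connectome(slice_connectome(conn, "outgoing", "K2"), "niche", "K3")
  expect_equal(edges_df(direct), edges_df(composed))
})

test_that("edge lists round-trip through CSV with provenance sidecar", {
  conn <- filter_connectome(random_connectome(4, 4, seed = 2),
                            min_frac = 0.2, max_p = 0.6)
  path <- tempfile(fileext = ".csv")
  write_edgelist(conn, path)
  back <- read_edgelist(path)
  expect_equal(edges_df(back), edges_df(conn))
  expect_equal(attr(back, "clusters"), attr(conn, "clusters"))
  expect_equal(attr(back, "mechanisms"), attr(conn, "mechanisms"))
  expect_equal(attr(back, "provenance")$filter$min_frac, 0.2)
})

test_that("reading degrades gracefully without a sidecar and errors on bad schema", {
  conn <- random_connectome(3, 2, seed = 4)
  path <- tempfile(fileext = ".csv")
  write_edgelist(conn, path)
  unlink(paste0(path, ".provenance.json"))
  expect_warning(back <- read_edgelist(path), "provenance")
  expect_equal(edges_df(back), edges_df(conn))
  df <- as.data.frame(conn)
  df$weight_scale <- NULL
  path2 <- tempfile(fileext = ".csv")
  write.csv(df, path2, row.names = FALSE)
  expect_error(read_edgelist(path2), "weight_scale")
})
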