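test_that("count simulation is a pure function of config and seed", {
  cfg <- simulation_config(n_genes = 50, group_sizes = c(A = 3, B = 4),
                           network_nodes = 10, seed = 42)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$size_factors, b$size_factors)
  expect_true(all(a$counts$counts >= 0))
  expect_true(all(a$counts$counts == round(a$counts$counts)))
  # different seed, different draw
  cfg2 <- simulation_config(n_genes = 50, group_sizes = c(A = 3, B = 4),
                            network_nodes = 10, seed = 43)
  expect_false(identical(simulate_counts(cfg2)$counts$counts,
                         a$counts$counts))
})

test_that("NB counts approach the Poisson limit as dispersion vanishes", {
  cfg <- simulation_config(n_genes = 20, group_sizes = c(A = 1000),
                           dispersion = 1e-8, baseline_log_sd = 0.5,
                           library_size_range = c(1, 1),
                           network_nodes = 2, seed = 5)
  m <- simulate_counts(cfg)$counts$counts
  ratio <- apply(m, 1, var) / rowMeans(m)
  expect_true(all(abs(ratio - 1) < 0.2))
})

test_that("NB variance follows Var = mu + alpha * mu^2", {
  cfg <- simulation_config(n_genes = 1, group_sizes = c(A = 20000),
                           dispersion = 0.5, baseline_log_mean = log(100),
                           baseline_log_sd = 1e-9,
                           library_size_range = c(1, 1),
                           network_nodes = 2, seed = 11)
  m <- simulate_counts(cfg)$counts$counts
  mu <- mean(m)
  expected <- mu + 0.5 * mu^2
  expect_lt(abs(var(as.numeric(m)) / expected - 1), 0.05)
})

test_that("planted log2 fold changes are recovered at large n", {
  pe <- data.frame(gene = "g0001", group = "B", log2fc = 2)
  cfg <- simulation_config(n_genes = 10, group_sizes = c(A = 200, B = 200),
                           planted_effects = pe,
                           library_size_range = c(1, 1),
                           network_nodes = 2, seed = 3)
  sim <- simulate_counts(cfg)
  m <- sim$counts$counts
  grp <- sim$counts$groups
  obs <- log2(mean(m["g0001", grp == "B"]) / mean(m["g0001", grp == "A"]))
  expect_lt(abs(obs - 2), 0.15)
  expect_identical(sim$truth_de$gene, "g0001")
})

test_that("planting an effect in an unknown group or with bad dispersion errors", {
  expect_error(simulation_config(dispersion = 0), "dispersion")
  expect_error(simulation_config(
    planted_effects = data.frame(gene = "g0001", group = "XX", log2fc = 1)),
    "unknown group")
})

test_that("simulated networks are weakly connected, heavy-tailed and seeded", {
  cfg <- simulation_config(n_genes = 500, network_nodes = 500, seed = 9)
  g <- simulate_network(cfg)
  expect_true(igraph::is_directed(g))
  expect_equal(igraph::count_components(g, mode = "weak"), 1)
  expect_identical(igraph::as_edgelist(g),
                   igraph::as_edgelist(simulate_network(cfg)))
  # preferential attachment: max total degree well above the median
  deg <- igraph::degree(g, mode = "all")
  expect_gt(max(deg), 5 * median(deg))
  # minimal graph: two nodes, one connected pair
  tiny <- simulation_config(n_genes = 2, network_nodes = 2,
                            network_edges_per_node = 1,
                            planted_module_size = 1, seed = 1)
  gt <- simulate_network(tiny)
  expect_equal(igraph::vcount(gt), 2)
  expect_equal(igraph::ecount(gt), 1)
})

test_that("module planting returns a connected set via BFS", {
  # path graph a-b-c-...-j: BFS from any start takes consecutive nodes
  ids <- sprintf("n%02d", 1:10)
  g <- igraph::graph_from_edgelist(cbind(ids[-10], ids[-1]), directed = TRUE)
  pm <- plant_perturbed_module(g, size = 5, log2fc = 2, group = "B", seed = 4)
  idx <- sort(match(pm$genes, ids))
  expect_equal(max(idx) - min(idx), 4)  # 5 consecutive nodes
  expect_equal(nrow(pm$effects), 5)
  expect_equal(unique(pm$effects$log2fc), 2)
  # size 1 is trivially fine; oversize errors
  expect_length(plant_perturbed_module(g, 1, 1, "B", seed = 1)$genes, 1)
  expect_error(plant_perturbed_module(g, 11, 1, "B"), "size")
})

test_that("planted modules are connected, disjoint and inside the study", {
  d <- demo_study(seed = 2)
  st <- d$study
  mods <- st$modules
  expect_true(all(lengths(mods) == c(20, 10, 10)))
  all_genes <- unlist(mods)
  expect_equal(anyDuplicated(all_genes), 0)
  expect_true(all(all_genes %in% rownames(st$counts$counts)))
  expect_true(all(all_genes %in% igraph::V(st$network)$name))
  for (m in mods) {
    sub <- igraph::induced_subgraph(st$network, m)
    expect_equal(igraph::count_components(sub, mode = "weak"), 1)
  }
  expect_true(all(st$truth_de$gene %in% rownames(st$counts$counts)))
})

test_that("fixture files round-trip the study exactly", {
  d <- demo_study(seed = 3)
  dir <- withr::local_tempdir()
  write_fixture(d$study, dir)
  back <- read_fixture(dir)
  expect_identical(back$counts$counts, d$study$counts$counts)
  expect_identical(back$counts$groups, d$study$counts$groups)
  expect_setequal(igraph::V(back$network)$name,
                  igraph::V(d$study$network)$name)
  el <- function(g) {
    e <- igraph::as_edgelist(g)
    sort(paste(e[, 1], e[, 2]))
  }
  expect_identical(el(back$network), el(d$study$network))
  expect_identical(back$gene_sets$sets[order(names(back$gene_sets$sets))],
                   d$study$gene_sets$sets[order(names(d$study$gene_sets$sets))])
  expect_identical(back$modules$module_RHD, d$study$modules$module_RHD)
  expect_equal(back$clinical$neutrophil_pct, d$study$clinical$neutrophil_pct,
               tolerance = 1e-12)
})

test_that("GMT format is read and written faithfully, including empty files", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sets.gmt")
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g2", "g4"))
  write_gmt(sets, path)
  lines <- readLines(path)
  expect_identical(lines[1], "alpha\tna\tg1\tg2\tg3")
  col <- read_gmt(path)
  expect_identical(col$sets, sets)
  # empty collection -> valid empty file
  write_gmt(list(), path)
  expect_identical(readLines(path), character(0))
  empty <- read_gmt(path)
  expect_length(empty$sets, 0)
})

test_that("clinical tables carry group-typical values", {
  cl <- simulate_clinical(c(ARF = 200, CHD = 200), seed = 8)
  expect_true(all(cl$neutrophil_pct > 0 & cl$neutrophil_pct < 100))
  expect_true(all(cl$lymphocyte_pct > 0))
  nlr <- compute_nlr(cl$neutrophil_pct, cl$lymphocyte_pct)
  # ARF runs a visibly higher NLR than the clinical control group
  expect_gt(mean(nlr[cl$group == "ARF"]), mean(nlr[cl$group == "CHD"]) + 0.3)
  expect_true(all(is.na(cl$crp[cl$group == "CHD"])))
})
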