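#' Configuration for a synthetic study
#'
#' Collects every knob of the synthetic-data generator. Defaults mirror a
#' small whole-blood RNA-seq cohort with four groups — a disease condition
#' (RHD), its precursor (ARF), a clinical control (CHD) and a small healthy
#' control (HC) of sizes 5/5/5/2 — so that small-n pathologies are exercised
#' by every downstream stage.
#'
#' Counts are negative binomial with the mean/dispersion parameterization
#' `Var = mu + dispersion * mu^2`; `dispersion` is therefore `1/size` in the
#' convention of [stats::rnbinom()].
#'
#' @param n_genes number of genes.
#' @param group_sizes named integer vector, samples per group.
#' @param baseline_log_mean,baseline_log_sd natural-log mean and sd of the
#'   per-gene baseline expression (baselines are log-normal).
#' @param dispersion NB dispersion, scalar or per-gene vector; must be > 0.
#' @param planted_effects data frame with columns `gene`, `group`, `log2fc`:
#'   genes whose mean is multiplied by `2^log2fc` in that group.
#' @param network_nodes number of network nodes (first `network_nodes` gene
#'   ids become node labels); must be at least 2.
#' @param network_edges_per_node preferential-attachment edges added per new
#'   node.
#' @param planted_module_size size of the default planted connected module.
#' @param library_size_range range of per-sample size factors, drawn
#'   log-uniform; set to `c(1, 1)` to disable library-size heterogeneity.
#' @param seed integer seed making every generator deterministic.
#' @return an object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_genes = 400,
                              group_sizes = c(ARF = 5, RHD = 5, CHD = 5, HC = 2),
                              baseline_log_mean = log(100),
                              baseline_log_sd = 1,
                              dispersion = 0.1,
                              planted_effects = NULL,
                              network_nodes = 300,
                              network_edges_per_node = 2,
                              planted_module_size = min(20, n_genes, network_nodes),
                              library_size_range = c(0.7, 1.4),
                              seed = 1L) {
  stopifnot(n_genes >= 1, length(group_sizes) >= 1, all(group_sizes >= 1),
            baseline_log_sd > 0, network_nodes >= 2,
            network_edges_per_node >= 1, planted_module_size >= 1,
            n_genes >= planted_module_size,
            length(library_size_range) == 2, all(library_size_range > 0))
  if (any(dispersion <= 0)) stop("dispersion must be positive")
  if (!length(dispersion) %in% c(1L, n_genes))
    stop("dispersion must be a scalar or one value per gene")
  if (is.null(names(group_sizes))) stop("group_sizes must be named")
  if (!is.null(planted_effects)) {
    planted_effects <- as.data.frame(planted_effects)
    stopifnot(all(c("gene", "group", "log2fc") %in% names(planted_effects)))
    bad <- setdiff(planted_effects$group, names(group_sizes))
    if (length(bad)) stop("unknown group in planted_effects: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(n_genes = as.integer(n_genes),
                 group_sizes = group_sizes,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 dispersion = dispersion,
                 planted_effects = planted_effects,
                 network_nodes = as.integer(network_nodes),
                 network_edges_per_node = as.integer(network_edges_per_node),
                 planted_module_size = as.integer(planted_module_size),
                 library_size_range = library_size_range,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

gene_ids <- function(n) sprintf("g%04d", seq_len(n))

sample_ids <- function(group_sizes) {
  unlist(lapply(names(group_sizes),
                function(g) sprintf("%s_%d", g, seq_len(group_sizes[[g]]))),
         use.names = FALSE)
}

#' Simulate a grouped negative-binomial count matrix
#'
#' Each gene gets a log-normal baseline mean; planted effects multiply the
#' mean by `2^log2fc` in their group; per-sample library-size factors are
#' drawn log-uniform from `config$library_size_range`. Counts are NB with
#' `Var = mu + dispersion * mu^2`.
#'
#' @param config a [simulation_config()].
#' @return a list with `counts` (a [count_matrix()]), `truth_de` (data frame
#'   `gene`, `group`, `log2fc` of planted effects) and `size_factors` (the
#'   true library-size factors).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    genes <- gene_ids(config$n_genes)
    samples <- sample_ids(config$group_sizes)
    groups <- stats::setNames(rep(names(config$group_sizes),
                                  config$group_sizes), samples)
    baseline <- exp(stats::rnorm(config$n_genes, config$baseline_log_mean,
                                 config$baseline_log_sd))
    sf <- exp(stats::runif(length(samples),
                           log(config$library_size_range[1]),
                           log(config$library_size_range[2])))
    beta <- matrix(0, config$n_genes, length(config$group_sizes),
                   dimnames = list(genes, names(config$group_sizes)))
    pe <- config$planted_effects
    if (!is.null(pe) && nrow(pe)) {
      bad <- setdiff(pe$gene, genes)
      if (length(bad)) stop("planted_effects gene not simulated: ",
                            paste(bad, collapse = ", "))
      beta[cbind(match(pe$gene, genes), match(pe$group, names(config$group_sizes)))] <-
        pe$log2fc
    }
    mu <- baseline * 2^beta[, groups, drop = FALSE]
    mu <- sweep(mu, 2, sf, `*`)
    disp <- rep_len(config$dispersion, config$n_genes)
    m <- matrix(stats::rnbinom(length(mu), mu = mu, size = rep(1 / disp, ncol(mu))),
                nrow = config$n_genes,
                dimnames = list(genes, samples))
    truth <- if (is.null(pe)) {
      data.frame(gene = character(), group = character(), log2fc = numeric())
    } else pe[, c("gene", "group", "log2fc")]
    list(counts = count_matrix(m, groups),
         truth_de = truth,
         size_factors = stats::setNames(sf, samples))
  })
}

#' Simulate a directed scale-free interaction network
#'
#' Grows an undirected preferential-attachment graph (heavy-tailed degrees,
#' as in curated protein-protein interaction networks), then assigns each
#' edge a direction uniformly at random. Node labels are the first
#' `network_nodes` gene ids of the count matrix, so the network and the
#' expression table share an id space by construction.
#'
#' @param config a [simulation_config()].
#' @return a directed [igraph::make_graph()] object with named vertices.
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed + 1L, {
    g <- igraph::sample_pa(config$network_nodes,
                           m = config$network_edges_per_node,
                           directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    flip <- stats::runif(nrow(el)) < 0.5
    el[flip, ] <- el[flip, 2:1]
    ids <- gene_ids(config$n_genes)[seq_len(config$network_nodes)]
    dg <- igraph::graph_from_edgelist(
      cbind(ids[el[, 1]], ids[el[, 2]]), directed = TRUE)
    dg <- igraph::simplify(dg, remove.multiple = TRUE, remove.loops = TRUE)
    # isolated vertices cannot appear with m >= 1, but keep the id universe
    igraph::add_vertices(dg, length(setdiff(ids, igraph::V(dg)$name)),
                         name = setdiff(ids, igraph::V(dg)$name))
  })
}

#' Plant a connected perturbed module in a network
#'
#' Chooses a connected (in the weak sense) set of nodes by breadth-first
#' expansion from a seeded start node and assigns each the given log2 fold
#' change in `group`. Used to create ground truth for TopNet recovery tests.
#'
#' @param network an igraph network with named vertices.
#' @param size module size.
#' @param log2fc planted log2 fold change for every module gene.
#' @param group group name receiving the effect.
#' @param seed integer seed choosing the start node.
#' @param exclude node names that may not be used (e.g. already planted).
#' @return a list with `genes` (ordered module members, BFS order) and
#'   `effects` (data frame `gene`, `group`, `log2fc`).
#' @export
plant_perturbed_module <- function(network, size, log2fc, group,
                                   seed = 1L, exclude = character()) {
  nodes <- igraph::V(network)$name
  if (size > length(nodes))
    stop("module size exceeds number of network nodes")
  avail <- setdiff(nodes, exclude)
  with_seed(seed, {
    starts <- sample(avail)
    for (s in starts) {
      # BFS over the undirected skeleton, never stepping on excluded nodes
      members <- s
      frontier <- s
      while (length(members) < size && length(frontier)) {
        nb <- unique(unlist(igraph::adjacent_vertices(network, frontier,
                                                      mode = "all")))
        nb <- setdiff(igraph::V(network)$name[nb], c(members, exclude))
        nb <- sort(nb)
        take <- utils::head(nb, size - length(members))
        members <- c(members, take)
        frontier <- take
      }
      if (length(members) == size) {
        return(list(genes = members,
                    effects = data.frame(gene = members, group = group,
                                         log2fc = log2fc)))
      }
    }
    stop("network has no connected set of ", size,
         " nodes avoiding the excluded set")
  })
}

#' Simulate random gene sets
#'
#' Draws `n_sets` random sets from the given universe and prepends any
#' `include` sets verbatim (e.g. a planted module, so over-representation of
#' the recovered signature is testable).
#'
#' @param genes universe of gene ids.
#' @param n_sets number of random sets.
#' @param set_size size of each random set.
#' @param seed integer seed.
#' @param include named list of fixed gene sets to prepend.
#' @return a [gene_set_collection()].
#' @export
simulate_gene_sets <- function(genes, n_sets = 10, set_size = 25,
                               seed = 1L, include = list()) {
  with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i)
      sort(sample(genes, min(set_size, length(genes)))))
    names(sets) <- sprintf("random_set_%02d", seq_len(n_sets))
    gene_set_collection(c(include, sets), universe = genes)
  })
}

# Group-level clinical reference values (means and SDs): disease groups
# follow published whole-blood profiles of ARF/RHD/CHD cohorts; HC uses
# textbook healthy-adult differentials. NA means the assay is not done for
# that group.
clinical_profiles <- function() {
  list(
    ARF = list(neutrophil = c(59.68, 12.28), lymphocyte = c(30.60, 11.01),
               esr = c(38.06, 24.75), crp = c(34.28, 31.54),
               aso = c(536.87, 199.28)),
    RHD = list(neutrophil = c(58.75, 12.22), lymphocyte = c(31.49, 11.53),
               esr = c(13.79, 9.89), crp = c(3.13, 2.31), aso = NA),
    CHD = list(neutrophil = c(48.48, 8.73), lymphocyte = c(37.04, 7.51),
               esr = c(13.41, 11.11), crp = NA, aso = NA),
    HC  = list(neutrophil = c(55, 8), lymphocyte = c(33, 7),
               esr = c(10, 5), crp = c(0.3, 0.2), aso = NA)
  )
}

#' Simulate a clinical blood-parameter table
#'
#' Per-sample neutrophil and lymphocyte percentages plus ESR, CRP and ASO,
#' drawn from group-specific normal distributions (truncated so percentages
#' stay in (0, 100) and positive quantities stay positive).
#'
#' @param group_sizes named integer vector, samples per group; group names
#'   must be among ARF, RHD, CHD, HC (others fall back to the HC profile).
#' @param seed integer seed.
#' @return data frame with columns `sample_id`, `group`, `neutrophil_pct`,
#'   `lymphocyte_pct`, `esr`, `crp`, `aso`.
#' @export
simulate_clinical <- function(group_sizes, seed = 1L) {
  prof <- clinical_profiles()
  with_seed(seed, {
    rows <- lapply(names(group_sizes), function(g) {
      n <- group_sizes[[g]]
      p <- prof[[g]] %||% prof$HC
      draw <- function(par, lo = 0, hi = Inf) {
        if (length(par) < 2 || anyNA(par)) return(rep(NA_real_, n))
        pmin(pmax(stats::rnorm(n, par[1], par[2]), lo), hi)
      }
      data.frame(sample_id = sprintf("%s_%d", g, seq_len(n)), group = g,
                 neutrophil_pct = draw(p$neutrophil, 1, 99),
                 lymphocyte_pct = draw(p$lymphocyte, 1, 99),
                 esr = draw(p$esr), crp = draw(p$crp), aso = draw(p$aso))
    })
    do.call(rbind, rows)
  })
}

#' Simulate a complete study with planted ground truth
#'
#' Generates, deterministically from `config$seed`: an interaction network;
#' one or more connected perturbed modules planted into designated groups;
#' an NB count matrix carrying those effects (plus any explicit
#' `planted_effects`); gene sets including one set per planted module; and a
#' clinical table.
#'
#' @param config a [simulation_config()].
#' @param modules list of module definitions, each a list with elements `group`,
#'   `size`, `log2fc`. The default plants one module of
#'   `config$planted_module_size` genes at log2fc 2 in group "RHD". Modules
#'   are planted on disjoint node sets.
#' @return an object of class `synthetic_study`: a list with `counts`,
#'   `network`, `gene_sets`, `truth_de`, `modules` (named list of gene
#'   vectors), `clinical`, and the `config`.
#' @export
simulate_study <- function(config = simulation_config(),
                           modules = list(list(group = "RHD",
                                               size = config$planted_module_size,
                                               log2fc = 2))) {
  stopifnot(inherits(config, "simulation_config"))
  network <- simulate_network(config)
  planted <- list()
  effects <- config$planted_effects
  used <- character()
  for (i in seq_along(modules)) {
    m <- modules[[i]]
    pm <- plant_perturbed_module(network, m$size, m$log2fc, m$group,
                                 seed = config$seed + 100L + i, exclude = used)
    planted[[sprintf("module_%s", m$group)]] <- pm$genes
    used <- c(used, pm$genes)
    effects <- rbind(effects, pm$effects)
  }
  cfg <- config
  cfg$planted_effects <- effects
  sim <- simulate_counts(cfg)
  include <- lapply(planted, identity)
  gene_sets <- simulate_gene_sets(rownames(sim$counts$counts),
                                  seed = config$seed + 2L, include = include)
  clinical <- simulate_clinical(config$group_sizes, seed = config$seed + 3L)
  structure(list(counts = sim$counts, network = network,
                 gene_sets = gene_sets, truth_de = sim$truth_de,
                 modules = planted, clinical = clinical, config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study: %d genes x %d samples, network %d nodes / %d edges\n",
              nrow(x$counts$counts), ncol(x$counts$counts),
              igraph::vcount(x$network), igraph::ecount(x$network)))
  for (nm in names(x$modules))
    cat(sprintf("  planted %s: %d genes\n", nm, length(x$modules[[nm]])))
  invisible(x)
}

#' Write a synthetic study to a directory of plain-text files
#'
#' Emits `counts.tsv`, `samples.tsv`, `network.sif` (tab-separated
#' `source<TAB>interaction<TAB>target`, interaction type `pp`),
#' `genesets.gmt`, `truth_de.tsv`, `modules.tsv` and `clinical.tsv`.
#' [read_fixture()] round-trips the study exactly.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_fixture <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_counts(study$counts, p("counts.tsv"), p("samples.tsv"))
  write_sif(study$network, p("network.sif"))
  write_gmt(study$gene_sets, p("genesets.gmt"))
  write_tsv(study$truth_de, p("truth_de.tsv"))
  mod <- do.call(rbind, lapply(names(study$modules), function(nm)
    data.frame(module = nm, gene = study$modules[[nm]])))
  write_tsv(mod %||% data.frame(module = character(), gene = character()),
            p("modules.tsv"))
  write_tsv(study$clinical, p("clinical.tsv"))
  invisible(dir)
}

#' Read a synthetic-study fixture written by [write_fixture()]
#'
#' @param dir directory holding the fixture files.
#' @return a list with `counts`, `network`, `gene_sets`, `truth_de`,
#'   `modules`, `clinical` (no `config`; files carry no generator state).
#' @export
read_fixture <- function(dir) {
  p <- function(f) file.path(dir, f)
  counts <- read_counts(p("counts.tsv"), p("samples.tsv"))
  mod_df <- read_tsv(p("modules.tsv"))
  modules <- split(mod_df$gene, mod_df$module)
  list(counts = counts,
       network = read_sif(p("network.sif")),
       gene_sets = read_gmt(p("genesets.gmt"),
                            universe = rownames(counts$counts)),
       truth_de = read_tsv(p("truth_de.tsv")),
       modules = modules[unique(mod_df$module)],
       clinical = read_tsv(p("clinical.tsv")))
}
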