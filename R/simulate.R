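#' Configuration for the structured-coalescent simulator
#'
#' Defines a dataset with the statistical structure the pipeline assumes:
#' several deep maternal clades (haplogroups), breeds whose samples coalesce
#' within the breed before joining their haplogroup's ancestral pool, and
#' optional introgression pulses that move a fraction of one breed's maternal
#' lineages into another breed's genealogy.
#'
#' Time is in coalescent units. Within a breed (and haplogroup), lineages
#' coalesce at Kingman rate `choose(k, 2) / within_depth` until `split_depth`,
#' when surviving lineages join the haplogroup-wide pool (rate
#' `choose(k, 2)`). Haplogroup ancestors then join along a fixed pectinate
#' backbone so clade identity is unambiguous across seeds.
#'
#' @param breeds Data.frame with columns `name` and `size`; default 20 breeds
#'   of 10 individuals.
#' @param n_haplogroups Number of deep clades, labeled A, B, C, ... (default 5).
#' @param haplogroup_mix Breeds x haplogroups matrix of mixture weights (rows
#'   sum to 1); default gives each breed weight 0.8 on a dominant haplogroup
#'   (cycling through the clades) and 0.2 spread over the rest.
#' @param theta Per-locus population mutation rate (default 5): mutations per
#'   lineage per coalescent unit = theta / 2, so a sample of two from one deme
#'   carries theta pairwise differences in expectation.
#' @param seq_length Alignment length in sites (default 789, a typical
#'   control-region alignment span).
#' @param split_depth Time at which breed lineages enter the haplogroup pool
#'   (default 10, deep enough that breeds are usually monophyletic).
#' @param within_depth Within-breed coalescent time scale (default 1).
#' @param introgression_pulses Data.frame with columns `donor`, `recipient`,
#'   `fraction` (may be empty): each pulse re-assigns the given fraction of
#'   the recipient's lineages (rounded, at least 1 when fraction > 0) to
#'   coalesce within the donor breed.
#' @param kappa HKY transition/transversion rate ratio (default 20, the
#'   strongly transition-biased regime of the mammalian control region).
#' @param gamma_shape Shape of the gamma distribution of among-site rate
#'   variation (default 0.2, strong heterogeneity; `Inf` = uniform rates).
#' @param base_freqs Stationary base frequencies (A, C, G, T).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(breeds = NULL, n_haplogroups = 5L, haplogroup_mix = NULL,
                       theta = 5, seq_length = 789L, split_depth = 10,
                       within_depth = 1, introgression_pulses = NULL,
                       kappa = 20, gamma_shape = 0.2,
                       base_freqs = c(A = 0.33, C = 0.26, G = 0.13, T = 0.28)) {
  if (is.null(breeds))
    breeds <- data.frame(name = sprintf("BR%02d", 1:20), size = 10L)
  stopifnot(all(c("name", "size") %in% names(breeds)),
            all(breeds$size >= 1L), !anyDuplicated(breeds$name),
            n_haplogroups >= 1L, theta >= 0, seq_length >= 1L,
            split_depth > 0, within_depth > 0)
  hg_names <- LETTERS[seq_len(n_haplogroups)]
  nb <- nrow(breeds)
  if (is.null(haplogroup_mix)) {
    haplogroup_mix <- matrix(if (n_haplogroups > 1L) 0.2 / (n_haplogroups - 1L) else 0,
                             nb, n_haplogroups)
    dom <- ((seq_len(nb) - 1L) %% n_haplogroups) + 1L
    for (i in seq_len(nb))
      haplogroup_mix[i, dom[i]] <- if (n_haplogroups > 1L) 0.8 else 1
  }
  haplogroup_mix <- as.matrix(haplogroup_mix)
  stopifnot(nrow(haplogroup_mix) == nb, ncol(haplogroup_mix) == n_haplogroups,
            all(haplogroup_mix >= 0),
            all(abs(rowSums(haplogroup_mix) - 1) < 1e-8))
  dimnames(haplogroup_mix) <- list(breeds$name, hg_names)
  if (is.null(introgression_pulses))
    introgression_pulses <- data.frame(donor = character(0),
                                       recipient = character(0),
                                       fraction = numeric(0))
  stopifnot(all(c("donor", "recipient", "fraction") %in% names(introgression_pulses)),
            all(introgression_pulses$fraction >= 0),
            all(introgression_pulses$fraction <= 1),
            all(introgression_pulses$donor %in% breeds$name),
            all(introgression_pulses$recipient %in% breeds$name))
  stopifnot(abs(sum(base_freqs) - 1) < 1e-8, length(base_freqs) == 4L)
  structure(list(breeds = breeds, n_haplogroups = as.integer(n_haplogroups),
                 haplogroup_names = hg_names, haplogroup_mix = haplogroup_mix,
                 theta = theta, seq_length = as.integer(seq_length),
                 split_depth = split_depth, within_depth = within_depth,
                 introgression_pulses = introgression_pulses,
                 kappa = kappa, gamma_shape = gamma_shape,
                 base_freqs = base_freqs),
            class = "sim_config")
}

# Kingman coalescent on a set of active lineage node-ids, from time t0,
# optionally capped at t_max. Returns updated state.
coalesce_lineages <- function(state, active, t0, t_max = Inf, scale = 1) {
  t <- t0
  while (length(active) > 1L) {
    k <- length(active)
    t <- t + stats::rexp(1L, rate = choose(k, 2) / scale)
    if (t > t_max) break
    pick <- sample(seq_len(k), 2L)
    state$n_nodes <- state$n_nodes + 1L
    id <- state$n_nodes
    state$height[id] <- t
    state$child1[id] <- active[pick[1L]]
    state$child2[id] <- active[pick[2L]]
    active <- c(active[-pick], id)
  }
  state$active <- active
  state
}

new_forest <- function(n_tips, labels) {
  list(n_nodes = n_tips, height = c(rep(0, n_tips)),
       child1 = rep(NA_integer_, n_tips), child2 = rep(NA_integer_, n_tips),
       labels = labels, active = NULL)
}

forest_join <- function(state, a, b, t) {
  state$n_nodes <- state$n_nodes + 1L
  id <- state$n_nodes
  state$height[id] <- t
  state$child1[id] <- a
  state$child2[id] <- b
  state
}

forest_newick <- function(state, root) {
  lab <- function(id) {
    if (id <= length(state$labels)) return(state$labels[id])
    ""
  }
  rec <- function(id) {
    if (is.na(state$child1[id])) return(lab(id))
    c1 <- state$child1[id]; c2 <- state$child2[id]
    paste0("(", rec(c1), ":", format(state$height[id] - state$height[c1], digits = 12),
           ",", rec(c2), ":", format(state$height[id] - state$height[c2], digits = 12),
           ")")
  }
  paste0(rec(root), ";")
}

#' Simulate a structured-coalescent genealogy with introgression pulses
#'
#' Samples each individual's haplogroup from its breed's mixture, applies the
#' introgression pulses (re-assigning lineages to the donor breed's genealogy
#' and haplogroup), coalesces lineages within breed-by-haplogroup demes up to
#' `split_depth`, then within each haplogroup pool, and finally joins the
#' haplogroup ancestors along a fixed pectinate backbone.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; the run is fully reproducible from it.
#' @return List with `tree` (a `phylo` with branch lengths in coalescent
#'   units) and `truth` (data.frame: `id`, `breed` as sampled,
#'   `genealogical_breed`, `haplogroup`, `introgressed`, `donor`).
#' @export
simulate_genealogy <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  br <- config$breeds
  truth <- do.call(rbind, lapply(seq_len(nrow(br)), function(i) {
    data.frame(id = sprintf("%s_%02d", br$name[i], seq_len(br$size[i])),
               breed = br$name[i], stringsAsFactors = FALSE)
  }))
  truth$genealogical_breed <- truth$breed
  truth$introgressed <- FALSE
  truth$donor <- NA_character_

  pulses <- config$introgression_pulses
  for (p in seq_len(nrow(pulses))) {
    frac <- pulses$fraction[p]
    if (frac == 0) next
    rec <- pulses$recipient[p]; don <- pulses$donor[p]
    rec_idx <- which(truth$breed == rec & !truth$introgressed)
    k <- max(1L, round(frac * length(rec_idx)))
    if (k >= length(rec_idx))
      stop("pulse fraction ", frac, " would move every lineage of ", rec)
    moved <- sample(rec_idx, k)
    truth$genealogical_breed[moved] <- don
    truth$introgressed[moved] <- TRUE
    truth$donor[moved] <- don
  }

  # haplogroup of each lineage follows its genealogical breed's mixture
  mix <- config$haplogroup_mix
  truth$haplogroup <- vapply(truth$genealogical_breed, function(b) {
    sample(config$haplogroup_names, 1L, prob = mix[b, ])
  }, character(1L))

  state <- new_forest(nrow(truth), truth$id)
  hg_pool <- stats::setNames(vector("list", config$n_haplogroups),
                             config$haplogroup_names)
  deme <- paste(truth$genealogical_breed, truth$haplogroup, sep = "\r")
  for (d in unique(deme)) {
    idx <- which(deme == d)
    state <- coalesce_lineages(state, idx, t0 = 0, t_max = config$split_depth,
                               scale = config$within_depth)
    hg <- truth$haplogroup[idx[1L]]
    hg_pool[[hg]] <- c(hg_pool[[hg]], state$active)
  }
  hg_roots <- c()
  hg_used <- names(hg_pool)[lengths(hg_pool) > 0L]
  for (hg in hg_used) {
    state <- coalesce_lineages(state, unlist(hg_pool[[hg]]),
                               t0 = config$split_depth, t_max = Inf, scale = 1)
    hg_roots[hg] <- state$active
  }
  # fixed pectinate backbone in haplogroup label order, above all coalescences
  base <- max(state$height) + config$split_depth
  root <- hg_roots[[1L]]
  if (length(hg_roots) > 1L) {
    for (k in 2L:length(hg_roots)) {
      state <- forest_join(state, root, hg_roots[[k]],
                           base + (k - 1L) * config$split_depth)
      root <- state$n_nodes
    }
  }
  tree <- parse_newick(forest_newick(state, root))
  list(tree = tree, truth = truth[, c("id", "breed", "genealogical_breed",
                                      "haplogroup", "introgressed", "donor")])
}

#' Evolve sequences along a genealogy under HKY with gamma rate variation
#'
#' Site-specific rate multipliers are drawn from a gamma distribution with
#' mean 1 (normalized), the root sequence from the stationary base
#' frequencies; mutation events are Poisson on each branch with rate
#' `theta / 2` per coalescent unit, hit sites proportionally to their rate,
#' and change the base according to the HKY jump kernel (transitions favored
#' by `kappa`).
#'
#' @param tree `phylo` with branch lengths in coalescent units.
#' @param theta Per-locus mutation rate (pairwise diversity scale).
#' @param kappa Transition/transversion rate ratio.
#' @param gamma_shape Gamma shape for among-site rates (`Inf` = uniform).
#' @param seq_length Number of sites.
#' @param base_freqs Stationary frequencies (A, C, G, T).
#' @param seed Integer seed.
#' @return Named character vector of tip sequences.
#' @export
mutate_hky_gamma <- function(tree, theta, kappa = 20, gamma_shape = 0.2,
                             seq_length = 789L,
                             base_freqs = c(A = 0.33, C = 0.26, G = 0.13, T = 0.28),
                             seed = 1L) {
  stopifnot(!is.null(tree$edge.length))
  set.seed(seed)
  L <- as.integer(seq_length)
  bases <- c("A", "C", "G", "T")
  rates <- if (is.finite(gamma_shape)) {
    r <- stats::rgamma(L, shape = gamma_shape, rate = gamma_shape)
    r / mean(r)
  } else rep(1, L)
  # HKY jump kernel: row = current base, columns = replacement weights
  is_transition <- matrix(FALSE, 4L, 4L, dimnames = list(bases, bases))
  is_transition["A", "G"] <- is_transition["G", "A"] <- TRUE
  is_transition["C", "T"] <- is_transition["T", "C"] <- TRUE
  kern <- matrix(rep(base_freqs, each = 4L), 4L, 4L, dimnames = list(bases, bases))
  kern[is_transition] <- kern[is_transition] * kappa
  diag(kern) <- 0
  kern <- kern / rowSums(kern)

  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  seqs <- matrix(NA_character_, nnode, L)
  root <- ntip + 1L
  seqs[root, ] <- sample(bases, L, replace = TRUE, prob = base_freqs)
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
    s <- seqs[par, ]
    nmut <- stats::rpois(1L, lambda = theta / 2 * ord$edge.length[e])
    if (nmut > 0L) {
      sites <- sample.int(L, nmut, replace = TRUE, prob = rates)
      for (site in sites) {
        s[site] <- sample(bases, 1L, prob = kern[s[site], ])
      }
    }
    seqs[child, ] <- s
  }
  out <- apply(seqs[seq_len(ntip), , drop = FALSE], 1L, paste, collapse = "")
  stats::setNames(out, tree$tip.label)
}

#' Simulate a complete dataset: genealogy, alignment, breed table, truth
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; genealogy and mutation streams are derived from it.
#' @return List of class `sim_result` with `alignment`, `breed_table`, `tree`,
#'   `truth`.
#' @export
simulate_dataset <- function(config, seed = 1L) {
  gen <- simulate_genealogy(config, seed = seed)
  aln <- mutate_hky_gamma(gen$tree, theta = config$theta, kappa = config$kappa,
                          gamma_shape = config$gamma_shape,
                          seq_length = config$seq_length,
                          base_freqs = config$base_freqs,
                          seed = seed + 101L)
  aln <- aln[gen$truth$id]  # sample order, not coalescent order
  regions <- c("Egypt", "East Tropical Africa", "Europe", "Western Asia",
               "Central Asia", "Eastern Asia")
  tails <- c("thin", "fat", "fat_rumped", "fat_base")
  br <- config$breeds
  breed_region <- stats::setNames(
    regions[((seq_len(nrow(br)) - 1L) %% length(regions)) + 1L], br$name)
  breed_tail <- stats::setNames(
    tails[((seq_len(nrow(br)) - 1L) %% length(tails)) + 1L], br$name)
  breed_table <- data.frame(id = gen$truth$id,
                            breed = gen$truth$breed,
                            region = unname(breed_region[gen$truth$breed]),
                            tail = unname(breed_tail[gen$truth$breed]),
                            stringsAsFactors = FALSE)
  structure(list(alignment = aln, breed_table = breed_table,
                 tree = gen$tree, truth = gen$truth),
            class = "sim_result")
}

#' Random binary coalescent tree for topology-statistic testing
#'
#' @param n_tips Number of tips (>= 2), labeled `T1..Tn`.
#' @param seed Integer seed.
#' @return A rooted binary `phylo`.
#' @export
random_binary_tree <- function(n_tips, seed = 1L) {
  stopifnot(n_tips >= 2L)
  set.seed(seed)
  tr <- ape::rcoal(n_tips)
  tr$tip.label <- paste0("T", seq_len(n_tips))
  tr
}
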