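# Synthetic-data generator emulating the study design: a curated reference
# world (four-rank Glomeromycota taxonomy over a species tree, with
# Paraglomus as the basal outgroup), intragenomic rRNA sequence variants as
# query ASVs, a greenhouse-style sampling design (genotypes x treatments x
# replicates, fixed read depth), and planted effects (taxon dropout,
# enrichment of a distant clade, a query-only novel lineage carrying a
# clade-exclusive insertion, off-target sequences on the outgroup side).
# Every output is consumable by the other modules, and ground truth is
# emitted for recovery tests.

# 24 genera with a plausible family/order backbone; Paraglomus (the most
# basal glomeromycotan branch) is kept last and serves as the outgroup.
GENUS_TABLE <- data.frame(
  genus = c("Glomus", "Rhizophagus", "Funneliformis", "Septoglomus",
            "Sclerocystis", "Dominikia", "Kamienskia", "Oehlia",
            "Claroideoglomus", "Albahypha",
            "Diversispora", "Corymbiglomus", "Redeckera",
            "Acaulospora", "Pacispora", "Sacculospora",
            "Gigaspora", "Scutellospora", "Cetraspora", "Racocetra",
            "Dentiscutata",
            "Archaeospora", "Ambispora",
            "Paraglomus"),
  family = c(rep("Glomeraceae", 8), rep("Claroideoglomeraceae", 2),
             rep("Diversisporaceae", 3), "Acaulosporaceae", "Pacisporaceae",
             "Sacculosporaceae", rep("Gigasporaceae", 5),
             "Archaeosporaceae", "Ambisporaceae", "Paraglomeraceae"),
  order = c(rep("Glomerales", 10), rep("Diversisporales", 6),
            rep("Gigasporales", 5), rep("Archaeosporales", 2),
            "Paraglomerales"),
  stringsAsFactors = FALSE)

AML1 <- "ATCAACTTTCGATGGTAGGATAGA"
AML2 <- "GAACCCAAACACTTTGGTTTCC"

default_effects <- function() {
  list(
    list(type = "dropout", rank = "genus", taxon = "Rhizophagus", treatment = "CM1x"),
    list(type = "enrichment", rank = "genus", taxon = "Ambispora",
         treatment = "CM1x", factor = 8),
    list(type = "novel_lineage", n_variants = 6, divergence = 0.08,
         insertion_len = 12, base_share = 0.15),
    list(type = "off_target", n = 3, divergence = 0.3)
  )
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions: ~800 bp AML1/AML2 amplicons,
#' 10,000 reads per sample, 4 genotypes x 3 treatment states x 5
#' replicates, a curated reference world of 174 sequences covering 91
#' species in 24 genera, species represented by up to dozens of
#' intragenomic sequence variants, and planted treatment effects.
#'
#' @param seed integer seed; all randomness derives from it.
#' @param n_genera,n_species,n_reference_seqs size of the reference world
#'   (`n_species <= n_reference_seqs <= 2 * n_species`).
#' @param amplicon_len amplicon length in bp (primer sites included).
#' @param variants_min,variants_max range of intragenomic variants per
#'   species.
#' @param variant_divergence substitutions/site between a variant and its
#'   species sequence.
#' @param indel_rate per-site indel event rate in variants (geometric
#'   lengths, mean 3).
#' @param genotypes,treatments,replicates the sampling design.
#' @param reads_per_sample exact read depth per sample.
#' @param concentration Dirichlet concentration tying replicates to their
#'   group composition (larger = more similar replicates).
#' @param effects list of planted effects; see [default_effects] in the
#'   package source for the shapes accepted (dropout, enrichment,
#'   novel_lineage, off_target).
#' @return an object of class `amf_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genera = 24L, n_species = 91L, n_reference_seqs = 174L,
                       amplicon_len = 800L,
                       variants_min = 1L, variants_max = 30L,
                       variant_divergence = 0.005, indel_rate = 5e-4,
                       genotypes = c("G.890", "G.935", "M.7", "M.26"),
                       treatments = c("PP", "C", "CM1x"),
                       replicates = 5L, reads_per_sample = 10000L,
                       concentration = 200,
                       effects = default_effects()) {
  stopifnot(n_genera >= 2, n_genera <= nrow(GENUS_TABLE),
            n_species >= n_genera, n_reference_seqs >= n_species,
            n_reference_seqs <= 2 * n_species,
            amplicon_len >= 100,
            variants_min >= 1, variants_max >= variants_min,
            variant_divergence >= 0, variant_divergence <= 1,
            indel_rate >= 0, indel_rate <= 1,
            replicates >= 2, reads_per_sample >= 1)
  structure(list(seed = as.integer(seed), n_genera = as.integer(n_genera),
                 n_species = as.integer(n_species),
                 n_reference_seqs = as.integer(n_reference_seqs),
                 amplicon_len = as.integer(amplicon_len),
                 variants_min = as.integer(variants_min),
                 variants_max = as.integer(variants_max),
                 variant_divergence = variant_divergence,
                 indel_rate = indel_rate,
                 genotypes = genotypes, treatments = treatments,
                 replicates = as.integer(replicates),
                 reads_per_sample = as.integer(reads_per_sample),
                 concentration = concentration,
                 effects = effects,
                 # divergence scales (substitutions/site) of the taxonomy tiers
                 bl_species = 0.02, bl_genus = 0.04, bl_family = 0.06,
                 bl_order = 0.10, ref_divergence = 0.002),
            class = "amf_sim_config")
}

# ---- sequence evolution ----------------------------------------------------

# JC-like substitution: expected `rate` substitutions/site over the free
# (non-primer) positions; each hit site changes to a uniform different base.
mutate_seq <- function(chars, rate, free_idx) {
  if (rate <= 0 || length(free_idx) == 0) return(chars)
  n <- stats::rpois(1, rate * length(free_idx))
  n <- min(n, length(free_idx))
  if (n == 0) return(chars)
  sites <- if (length(free_idx) == 1) free_idx else sample(free_idx, n)
  bases <- c("A", "C", "G", "T")
  chars[sites] <- vapply(chars[sites],
                         function(b) sample(bases[bases != b], 1), character(1))
  chars
}

rand_bl <- function(mean) mean * stats::runif(1, 0.5, 1.5)

# length-safe single draw (sample() on a length-1 vector samples 1:x)
sample1 <- function(x) x[sample.int(length(x), 1)]

# random binary join of a list of subtree nodes; internal branch lengths
# drawn around `bl_mean`
rand_binary <- function(nodes, bl_mean) {
  while (length(nodes) > 2) {
    i <- sample(length(nodes), 2)
    joined <- list(label = "", bl = rand_bl(bl_mean), children = nodes[i])
    nodes <- c(nodes[-i], list(joined))
  }
  nodes
}

new_tip <- function(label, bl) list(label = label, bl = bl, children = NULL)

# collapse degree-2 (single-child) internal nodes, summing branch lengths,
# so the emitted newick is a proper tree
simplify_node <- function(node) {
  if (is.null(node$children)) return(node)
  node$children <- lapply(node$children, simplify_node)
  if (length(node$children) == 1) {
    ch <- node$children[[1]]
    ch$bl <- ch$bl + node$bl
    return(ch)
  }
  node
}

# nested-list tree -> newick text (tip labels only; no internal labels)
tree_to_newick <- function(node) {
  node$children <- lapply(node$children, simplify_node)
  render <- function(nd) {
    if (is.null(nd$children)) {
      paste0(nd$label, ":", format(nd$bl, digits = 10, scientific = FALSE))
    } else {
      paste0("(", paste(vapply(nd$children, render, character(1)), collapse = ","),
             "):", format(nd$bl, digits = 10, scientific = FALSE))
    }
  }
  paste0("(", paste(vapply(node$children, render, character(1)), collapse = ","), ");")
}

# ---- reference world -------------------------------------------------------

#' Simulate the curated reference world
#'
#' Builds a species tree with the four-rank taxonomy nested along it
#' (orders > families > genera > species; Paraglomerales basal), evolves an
#' ~`amplicon_len` bp amplicon (AML1/AML2 primer sites planted at the ends
#' and held invariant) down the tree by JC-like substitutions, and draws
#' the reference sequences for each species.  Reference counts, source-set
#' split, and type-culture flags follow the configured set size.
#'
#' @param cfg an [sim_config()].
#' @return a list (class `amf_sim_world`) with elements `species`
#'   (data.frame), `references` (a reference set as in
#'   [load_references()]), `species_tree` (`phylo`, tips = species keys),
#'   `treelist` (internal nested tree carrying node sequences), `free_idx`
#'   (mutable positions), and `cfg`.
#' @export
simulate_reference_world <- function(cfg) {
  stopifnot(inherits(cfg, "amf_sim_config"))
  set.seed(cfg$seed)
  L <- cfg$amplicon_len
  npf <- nchar(AML1); npr <- nchar(AML2)
  root_seq <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  root_seq[seq_len(npf)] <- strsplit(AML1, "")[[1]]
  root_seq[(L - npr + 1):L] <- strsplit(revcomp(AML2), "")[[1]]
  free_idx <- (npf + 1):(L - npr)

  # genera: keep Paraglomus (last row) always, fill the rest in table order
  others <- GENUS_TABLE[GENUS_TABLE$genus != "Paraglomus", , drop = FALSE]
  genera <- rbind(others[seq_len(cfg$n_genera - 1L), , drop = FALSE],
                  GENUS_TABLE[GENUS_TABLE$genus == "Paraglomus", , drop = FALSE])
  base_sp <- cfg$n_species %/% cfg$n_genera
  extra <- cfg$n_species %% cfg$n_genera
  n_sp <- rep(base_sp, cfg$n_genera) + c(rep(1L, extra), rep(0L, cfg$n_genera - extra))

  species <- do.call(rbind, lapply(seq_len(nrow(genera)), function(gi) {
    data.frame(genus = genera$genus[gi], family = genera$family[gi],
               order = genera$order[gi],
               species = paste(genera$genus[gi], sprintf("sp%02d", seq_len(n_sp[gi]))),
               stringsAsFactors = FALSE)
  }))
  species$species_key <- gsub(" ", "_", species$species, fixed = TRUE)
  n_two <- cfg$n_reference_seqs - cfg$n_species
  species$n_refs <- c(rep(2L, n_two), rep(1L, cfg$n_species - n_two))

  # nested tree: root = (ingroup orders..., Paraglomerales)
  genus_node <- function(g) {
    keys <- species$species_key[species$genus == g]
    tips <- lapply(keys, function(k) new_tip(k, rand_bl(cfg$bl_species)))
    list(label = g, bl = rand_bl(cfg$bl_genus),
         children = if (length(tips) == 1) tips else rand_binary(tips, cfg$bl_species))
  }
  family_node <- function(f) {
    gs <- unique(genera$genus[genera$family == f])
    kids <- lapply(gs, genus_node)
    list(label = f, bl = rand_bl(cfg$bl_family),
         children = if (length(kids) == 1) kids else rand_binary(kids, cfg$bl_genus))
  }
  order_node <- function(o) {
    fs <- unique(genera$family[genera$order == o])
    kids <- lapply(fs, family_node)
    list(label = o, bl = rand_bl(cfg$bl_order),
         children = if (length(kids) == 1) kids else rand_binary(kids, cfg$bl_family))
  }
  in_orders <- setdiff(unique(genera$order), "Paraglomerales")
  ingroup_kids <- lapply(in_orders, order_node)
  ingroup <- list(label = "ingroup", bl = rand_bl(cfg$bl_order),
                  children = if (length(ingroup_kids) == 1) ingroup_kids
                             else rand_binary(ingroup_kids, cfg$bl_order))
  basal <- order_node("Paraglomerales")
  basal$bl <- rand_bl(cfg$bl_order)
  treelist <- list(label = "root", bl = 0,
                   children = list(basal, ingroup), seq = root_seq)

  # evolve sequences down the nested tree
  evolve <- function(node, parent_seq) {
    node$seq <- mutate_seq(parent_seq, node$bl, free_idx)
    if (!is.null(node$children))
      node$children <- lapply(node$children, evolve, parent_seq = node$seq)
    node
  }
  treelist$children <- lapply(treelist$children, evolve, parent_seq = root_seq)

  # collect species (tip) sequences
  sp_seqs <- new.env(parent = emptyenv())
  walk <- function(node) {
    if (is.null(node$children)) assign(node$label, node$seq, envir = sp_seqs)
    else lapply(node$children, walk)
    invisible(NULL)
  }
  walk(treelist)
  species$sequence <- vapply(species$species_key,
                             function(k) paste(get(k, envir = sp_seqs), collapse = ""),
                             character(1))

  # draw reference sequences per species
  refs <- do.call(rbind, lapply(seq_len(nrow(species)), function(si) {
    sp <- species[si, ]
    data.frame(seq_id = paste0(sp$species_key, "_ref", seq_len(sp$n_refs)),
               species_key = sp$species_key, stringsAsFactors = FALSE)
  }))
  sp_chars <- lapply(species$species_key, function(k) get(k, envir = sp_seqs))
  names(sp_chars) <- species$species_key
  refs$sequence <- vapply(refs$species_key, function(k)
    paste(mutate_seq(sp_chars[[k]], cfg$ref_divergence, free_idx), collapse = ""),
    character(1))
  si <- match(refs$species_key, species$species_key)
  refs$order <- species$order[si]; refs$family <- species$family[si]
  refs$genus <- species$genus[si]; refs$species <- species$species[si]
  n_b <- if (nrow(refs) >= 56) 28L else ceiling(nrow(refs) / 6)
  refs$source_set <- c(rep("set_A", nrow(refs) - n_b), rep("set_B", n_b))
  refs$is_type_culture <- seq_len(nrow(refs)) <= min(21L, nrow(refs))
  references <- refs[c("seq_id", "sequence", "order", "family", "genus",
                       "species", "is_type_culture", "source_set")]
  rownames(references) <- NULL
  validate_reference_set(references)

  species_tree <- parse_newick(tree_to_newick(treelist))
  structure(list(cfg = cfg, species = species, references = references,
                 species_tree = species_tree, treelist = treelist,
                 sp_chars = sp_chars, root_seq = root_seq, free_idx = free_idx),
            class = "amf_sim_world")
}

# ---- intragenomic variants -------------------------------------------------

#' Simulate intragenomic rRNA variants of one species
#'
#' Each variant carries Poisson(`variant_divergence` x length)
#' substitutions and Poisson(`indel_rate` x length) indel events of
#' geometric length (mean 3; deletions become gap runs, insertions are
#' recorded as events so the true alignment can be reconstructed).  The
#' number of variants defaults to a uniform draw over the configured range,
#' emulating the dozens of sequence variants a single spore can carry.
#'
#' @param species_seq species sequence (string, or character vector of
#'   single bases).
#' @param cfg an [sim_config()].
#' @param n number of variants (default: uniform over
#'   `variants_min:variants_max`).
#' @param free_idx mutable positions (default: everything).
#' @return a list of variants, each a list with `chars` (master-coordinate
#'   character vector, deletions as `"-"`) and `insertions` (list of
#'   `list(pos, seq)` events).
#' @export
simulate_intragenomic_variants <- function(species_seq, cfg, n = NULL,
                                           free_idx = NULL) {
  chars0 <- if (length(species_seq) == 1) strsplit(species_seq, "")[[1]] else species_seq
  L <- length(chars0)
  if (is.null(free_idx)) free_idx <- seq_len(L)
  if (is.null(n))
    n <- sample1(seq(cfg$variants_min, cfg$variants_max))
  lapply(seq_len(n), function(v) {
    chars <- mutate_seq(chars0, cfg$variant_divergence, free_idx)
    insertions <- list()
    n_ev <- stats::rpois(1, cfg$indel_rate * L)
    for (e in seq_len(n_ev)) {
      len <- stats::rgeom(1, 1 / 3) + 1L
      if (stats::runif(1) < 0.5) {            # deletion: gap run
        pos <- sample1(free_idx)
        run <- intersect(pos:(pos + len - 1L), free_idx)
        chars[run] <- "-"
      } else {                                 # insertion: recorded event
        pos <- sample1(free_idx)
        insertions <- c(insertions, list(list(
          pos = pos, seq = sample(c("A", "C", "G", "T"), len, replace = TRUE))))
      }
    }
    list(chars = chars, insertions = insertions)
  })
}

# splice insertion events into the ungapped sequence of one variant
assemble_ungapped <- function(chars, insertions) {
  res <- chars != "-"
  base <- chars[res]
  if (length(insertions) > 0) {
    cum <- cumsum(res)
    ord <- order(vapply(insertions, `[[`, numeric(1), "pos"), decreasing = TRUE)
    for (ev in insertions[ord]) {
      at <- cum[ev$pos]
      base <- append(base, ev$seq, after = at)
    }
  }
  paste(base, collapse = "")
}

# build the true gapped alignment: master columns plus one column block per
# insertion event.  `rows` is a named list of master-coordinate character
# vectors; `events` a list of list(pos, seq, rows = row ids sharing it).
assemble_alignment <- function(rows, events) {
  ids <- names(rows)
  base <- do.call(rbind, rows)
  rownames(base) <- ids
  if (length(events) == 0) return(msa(base))
  ord <- order(vapply(events, `[[`, numeric(1), "pos"))
  events <- events[ord]
  pieces <- list()
  prev <- 0L
  for (ev in events) {
    if (ev$pos > prev) {
      pieces <- c(pieces, list(base[, (prev + 1L):ev$pos, drop = FALSE]))
      prev <- ev$pos
    }
    block <- matrix("-", nrow = length(ids), ncol = length(ev$seq),
                    dimnames = list(ids, NULL))
    block[ev$rows, ] <- matrix(ev$seq, nrow = length(ev$rows),
                               ncol = length(ev$seq), byrow = TRUE)
    pieces <- c(pieces, list(block))
  }
  if (prev < ncol(base))
    pieces <- c(pieces, list(base[, (prev + 1L):ncol(base), drop = FALSE]))
  msa(do.call(cbind, pieces))
}

# ---- communities -----------------------------------------------------------

#' Simulate communities, query ASVs, true tree and true alignment
#'
#' Draws, for each genotype, a base species composition (Dirichlet), applies
#' the planted treatment effects (dropout, enrichment, novel-lineage and
#' off-target injection), ties replicates to their group composition with a
#' Dirichlet of the configured concentration, and allocates exactly
#' `reads_per_sample` reads multinomially to species and then to their
#' intragenomic variants.  The novel lineage appears only among the queries
#' (never in the reference output) and carries a clade-exclusive insertion;
#' off-target sequences branch on the outgroup side of the root.
#'
#' @param cfg an [sim_config()].
#' @param world result of [simulate_reference_world()].
#' @return a list (class `amf_sim_community`) with `counts` (samples x ASVs
#'   integer matrix), `meta` (sample metadata), `queries` (data.frame
#'   asv_id/sequence), `msa` (true alignment over reference + query tips),
#'   `tree` (rooted true `phylo`), and `ground_truth` (list: `asv_table`
#'   mapping each ASV to its true species / "novel" / "off_target",
#'   `outgroup_tips`, `novel_asv_ids`, `off_target_ids`, `effects`).
#' @export
simulate_communities <- function(cfg, world) {
  stopifnot(inherits(cfg, "amf_sim_config"), inherits(world, "amf_sim_world"))
  set.seed(cfg$seed + 1L)
  species <- world$species
  free_idx <- world$free_idx

  eff_of <- function(type) Filter(function(e) e$type == type, cfg$effects)
  for (e in c(eff_of("dropout"), eff_of("enrichment"))) {
    pool <- if (identical(e$rank, "genus")) species$genus else species$species
    if (!(e$taxon %in% pool))
      stop("planted effect references unknown taxon: ", e$taxon)
  }

  in_sp <- species[species$order != "Paraglomerales", , drop = FALSE]

  # intragenomic variants per ingroup species
  var_list <- lapply(seq_len(nrow(in_sp)), function(si)
    simulate_intragenomic_variants(world$sp_chars[[in_sp$species_key[si]]],
                                   cfg, free_idx = free_idx))
  names(var_list) <- in_sp$species_key

  # planted novel lineage: evolved from an ingroup family ancestor, with a
  # clade-exclusive insertion shared by all of its variants
  novel <- NULL
  ne <- eff_of("novel_lineage")
  if (length(ne) > 0) {
    ne <- ne[[1]]
    donor <- world$sp_chars[[in_sp$species_key[1]]]
    anc <- mutate_seq(donor, ne$divergence, free_idx)
    ins_pos <- sample1(free_idx[free_idx > min(free_idx) + 10 &
                                  free_idx < max(free_idx) - 10])
    ins_seq <- sample(c("A", "C", "G", "T"), ne$insertion_len, replace = TRUE)
    novel <- list(variants = lapply(seq_len(ne$n_variants), function(v)
                    mutate_seq(anc, cfg$variant_divergence, free_idx)),
                  ins_pos = ins_pos, ins_seq = ins_seq,
                  base_share = ne$base_share,
                  donor_family = in_sp$family[1])
  }

  # planted off-target lineage on the outgroup side
  off <- NULL
  oe <- eff_of("off_target")
  if (length(oe) > 0) {
    oe <- oe[[1]]
    anc <- mutate_seq(world$root_seq, oe$divergence, free_idx)
    off <- list(variants = lapply(seq_len(oe$n), function(v)
      mutate_seq(anc, 0.02, free_idx)), divergence = oe$divergence)
  }

  # ASV ids, in order: species variants, novel variants, off-target
  asv_rows <- list()
  truth <- list()
  for (k in names(var_list)) {
    sp <- species[species$species_key == k, ]
    for (v in seq_along(var_list[[k]])) {
      asv_rows <- c(asv_rows, list(var_list[[k]][[v]]))
      truth <- c(truth, list(data.frame(origin = "species", species_key = k,
                                        species = sp$species, genus = sp$genus,
                                        stringsAsFactors = FALSE)))
    }
  }
  n_sp_asv <- length(asv_rows)
  if (!is.null(novel)) {
    for (v in seq_along(novel$variants)) {
      asv_rows <- c(asv_rows, list(list(chars = novel$variants[[v]],
                                        insertions = list())))
      truth <- c(truth, list(data.frame(origin = "novel", species_key = NA,
                                        species = NA, genus = NA)))
    }
  }
  n_novel <- if (is.null(novel)) 0L else length(novel$variants)
  if (!is.null(off)) {
    for (v in seq_along(off$variants)) {
      asv_rows <- c(asv_rows, list(list(chars = off$variants[[v]],
                                        insertions = list())))
      truth <- c(truth, list(data.frame(origin = "off_target", species_key = NA,
                                        species = NA, genus = NA)))
    }
  }
  asv_ids <- paste0("ASV", seq_along(asv_rows))
  truth <- cbind(data.frame(asv_id = asv_ids, stringsAsFactors = FALSE),
                 do.call(rbind, truth))
  novel_ids <- if (n_novel > 0) asv_ids[n_sp_asv + seq_len(n_novel)] else character(0)
  off_ids <- if (!is.null(off))
    asv_ids[(n_sp_asv + n_novel + 1):length(asv_ids)] else character(0)

  # true tree: species tips replaced by (refs + variants), novel clade
  # grafted at its donor family, off-target grafted on the outgroup side
  vt_of <- function(k) {
    sp <- species[species$species_key == k, ]
    kids <- lapply(seq_len(sp$n_refs), function(r)
      new_tip(paste0(k, "_ref", r), cfg$ref_divergence))
    vids <- truth$asv_id[!is.na(truth$species_key) & truth$species_key == k]
    kids <- c(kids, lapply(vids, function(a) new_tip(a, cfg$variant_divergence)))
    kids
  }
  graft <- function(node) {
    if (is.null(node$children)) {
      k <- node$label
      return(list(label = k, bl = node$bl, children = vt_of(k)))
    }
    node$children <- lapply(node$children, graft)
    if (!is.null(novel) && identical(node$label, novel$donor_family)) {
      nc <- list(label = "novel", bl = ne$divergence,
                 children = lapply(novel_ids, function(a)
                   new_tip(a, cfg$variant_divergence)))
      node$children <- c(node$children, list(nc))
    }
    node
  }
  treelist <- world$treelist
  treelist$children <- lapply(treelist$children, graft)
  if (!is.null(off)) {
    ot <- list(label = "off_target", bl = off$divergence,
               children = lapply(off_ids, function(a) new_tip(a, 0.02)))
    basal <- list(label = "basal", bl = 0.02,
                  children = list(treelist$children[[1]], ot))
    treelist$children <- c(list(basal), treelist$children[-1])
  }
  tree <- parse_newick(tree_to_newick(treelist))
  # outgroup side = the root child containing the Paraglomerales references
  pg_ref <- species$species_key[species$order == "Paraglomerales"][1]
  pg_tip <- grep(paste0("^", pg_ref, "_ref"), tree$tip.label, value = TRUE)[1]
  root_kids <- tree$edge[tree$edge[, 1] == ape::Ntip(tree) + 1L, 2]
  kid_tips <- phangorn::Descendants(tree, root_kids, type = "tips")
  og_kid <- which(vapply(kid_tips, function(tt) pg_tip %in% tree$tip.label[tt],
                         logical(1)))[1]
  outgroup_tips <- tree$tip.label[kid_tips[[og_kid]]]

  # true alignment over reference + query tips
  ref_chars <- lapply(world$references$sequence, function(s) strsplit(s, "")[[1]])
  names(ref_chars) <- world$references$seq_id
  q_chars <- lapply(asv_rows, `[[`, "chars")
  names(q_chars) <- asv_ids
  events <- list()
  for (i in seq_along(asv_rows)) {
    for (ev in asv_rows[[i]]$insertions)
      events <- c(events, list(list(pos = ev$pos, seq = ev$seq, rows = asv_ids[i])))
  }
  if (!is.null(novel))
    events <- c(events, list(list(pos = novel$ins_pos, seq = novel$ins_seq,
                                  rows = novel_ids)))
  aln <- assemble_alignment(c(ref_chars, q_chars), events)

  queries <- data.frame(asv_id = asv_ids,
                        sequence = vapply(asv_rows, function(r)
                          assemble_ungapped(r$chars, r$insertions), character(1)),
                        stringsAsFactors = FALSE)
  # novel-lineage ungapped sequences carry the shared insertion
  if (n_novel > 0) {
    for (a in novel_ids) {
      i <- match(a, asv_ids)
      queries$sequence[i] <- assemble_ungapped(
        asv_rows[[i]]$chars, list(list(pos = novel$ins_pos, seq = novel$ins_seq)))
    }
  }

  # community composition and counts
  taxa <- in_sp$species_key
  weights <- lapply(taxa, function(k) {
    w <- stats::rgamma(length(var_list[[k]]), 5); w / sum(w)
  })
  names(weights) <- taxa
  ot_share <- if (is.null(off)) 0 else 0.01
  nv_share <- if (is.null(novel)) 0 else novel$base_share
  samples <- expand.grid(replicate = seq_len(cfg$replicates),
                         treatment = cfg$treatments, genotype = cfg$genotypes,
                         stringsAsFactors = FALSE)[c("genotype", "treatment", "replicate")]
  samples$sample_id <- paste(samples$genotype, samples$treatment,
                             samples$replicate, sep = "_")
  counts <- matrix(0L, nrow = nrow(samples), ncol = length(asv_ids),
                   dimnames = list(samples$sample_id, asv_ids))
  for (g in cfg$genotypes) {
    base <- stats::rgamma(length(taxa), 0.4)
    base <- base / sum(base) * (1 - nv_share - ot_share)
    novel_g <- if (is.null(novel)) 0 else nv_share * stats::runif(1, 0.3, 1.7)
    for (tr in cfg$treatments) {
      mass <- base
      for (e in eff_of("dropout")) if (identical(e$treatment, tr)) {
        hit <- if (identical(e$rank, "genus")) in_sp$genus == e$taxon
               else in_sp$species == e$taxon
        mass[hit] <- 0
      }
      for (e in eff_of("enrichment")) if (identical(e$treatment, tr)) {
        hit <- if (identical(e$rank, "genus")) in_sp$genus == e$taxon
               else in_sp$species == e$taxon
        mass[hit] <- mass[hit] * e$factor
      }
      full <- c(mass,
                if (n_novel > 0) novel_g,
                if (length(off_ids) > 0)
                  rep(ot_share / length(off_ids), length(off_ids)))
      full <- full / sum(full)
      for (r in seq_len(cfg$replicates)) {
        a <- stats::rgamma(length(full), shape = cfg$concentration * full)
        comp <- if (sum(a) == 0) full else a / sum(a)
        p_asv <- numeric(length(asv_ids))
        for (ti in seq_along(taxa)) {
          vids <- truth$asv_id[!is.na(truth$species_key) &
                                 truth$species_key == taxa[ti]]
          p_asv[match(vids, asv_ids)] <- comp[ti] * weights[[ti]]
        }
        if (n_novel > 0) {
          wn <- stats::rgamma(n_novel, 5); wn <- wn / sum(wn)
          p_asv[match(novel_ids, asv_ids)] <- comp[length(taxa) + 1] * wn
        }
        if (length(off_ids) > 0)
          p_asv[match(off_ids, asv_ids)] <-
            comp[(length(comp) - length(off_ids) + 1):length(comp)]
        sid <- paste(g, tr, r, sep = "_")
        counts[sid, ] <- as.integer(
          stats::rmultinom(1, cfg$reads_per_sample, p_asv))
      }
    }
  }

  structure(list(counts = counts,
                 meta = samples[c("sample_id", "genotype", "treatment", "replicate")],
                 queries = queries, msa = aln, tree = tree,
                 ground_truth = list(asv_table = truth,
                                     outgroup_tips = outgroup_tips,
                                     novel_asv_ids = novel_ids,
                                     off_target_ids = off_ids,
                                     effects = cfg$effects)),
            class = "amf_sim_community")
}

# ---- emission / loading ----------------------------------------------------

#' Write a complete synthetic dataset to disk
#'
#' Emits reference FASTA + taxonomy TSV (combined and split by source set),
#' query FASTA, true gapped alignment, true rooted tree (newick), counts
#' TSV, sample metadata TSV, a ground-truth table and a JSON manifest.  All
#' files reload through the package's own loaders.
#'
#' @param world result of [simulate_reference_world()].
#' @param communities result of [simulate_communities()].
#' @param outdir output directory (created if needed).
#' @return named list of the written paths.
#' @export
emit_dataset <- function(world, communities, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  p <- function(f) file.path(outdir, f)
  refs <- world$references
  write_references(refs, p("reference_taxonomy.tsv"), p("reference.fasta"))
  for (ss in unique(refs$source_set)) {
    sub <- refs[refs$source_set == ss, , drop = FALSE]
    write_references(sub, p(paste0("reference_taxonomy_", ss, ".tsv")),
                     p(paste0("reference_", ss, ".fasta")))
  }
  write_fasta(stats::setNames(communities$queries$sequence,
                              communities$queries$asv_id), p("queries.fasta"))
  write_msa(communities$msa, p("alignment.fasta"))
  write_newick(communities$tree, p("tree.nwk"))
  write_count_table(communities$counts, p("counts.tsv"))
  write_tsv(communities$meta, p("sample_metadata.tsv"))
  write_tsv(communities$ground_truth$asv_table, p("ground_truth.tsv"))
  jsonlite::write_json(list(seed = world$cfg$seed,
                            outgroup_tips = communities$ground_truth$outgroup_tips,
                            novel_asv_ids = communities$ground_truth$novel_asv_ids,
                            off_target_ids = communities$ground_truth$off_target_ids,
                            effects = communities$ground_truth$effects),
                       p("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(reference_taxonomy = p("reference_taxonomy.tsv"),
                 reference_fasta = p("reference.fasta"),
                 queries = p("queries.fasta"), alignment = p("alignment.fasta"),
                 tree = p("tree.nwk"), counts = p("counts.tsv"),
                 metadata = p("sample_metadata.tsv"),
                 ground_truth = p("ground_truth.tsv"),
                 manifest = p("manifest.json")))
}

#' Reload an emitted synthetic dataset
#'
#' @param outdir directory written by [emit_dataset()].
#' @return a list with references, queries, msa, tree, counts, meta and the
#'   manifest.
#' @export
load_dataset <- function(outdir) {
  p <- function(f) file.path(outdir, f)
  list(references = load_references(p("reference_taxonomy.tsv"), p("reference.fasta")),
       queries = load_queries(p("queries.fasta")),
       msa = read_msa(p("alignment.fasta")),
       tree = parse_newick(p("tree.nwk")),
       counts = read_count_table(p("counts.tsv")),
       meta = read_sample_meta(p("sample_metadata.tsv")),
       ground_truth = read_tsv(p("ground_truth.tsv")),
       manifest = jsonlite::read_json(p("manifest.json"), simplifyVector = TRUE))
}
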