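#' Configuration of the synthetic benchmark generator
#'
#' The generator emulates the structure of a curated drug-disease
#' knowledge graph: drugs and diseases belong to latent mechanism
#' clusters; feature vocabularies (substructures, targets, domains, ATC
#' codes, genes, classes, types, semantic types) are partitioned over the
#' same clusters; edges prefer within-cluster items (probability `p_in`)
#' over cross-cluster ones (`p_out`); therapeutic associations arise at
#' rate `treat_prob_in` within a cluster and `treat_prob_out` across; a
#' fraction of the side-effect vocabulary is identity-mapped to disease
#' identifiers so the adverse-reaction negative rule can fire, and
#' side-effect draws prefer disease-mapped terms of *other* clusters
#' (probability `sidefx_cross_bias`), making the resulting negatives
#' truly non-associated. Gene-encodes-target edges wire disease genes to
#' drug targets within clusters — the planted mechanism signal.
#'
#' @param n_drugs,n_diseases Entity counts (defaults 60 and 25).
#' @param n_clusters Latent mechanism groups (default 4).
#' @param vocab Named list of feature vocabulary sizes.
#' @param p_in,p_out Within-/cross-cluster edge probabilities
#'   (`0 <= p_out < p_in <= 1`).
#' @param treat_prob_in,treat_prob_out Association rates within/across
#'   clusters.
#' @param sidefx_disease_overlap Fraction of the side-effect vocabulary
#'   identity-mapped to disease ids (must be positive for negatives to
#'   exist).
#' @param sidefx_cross_bias Probability that a side-effect draw targets a
#'   disease-mapped term from another cluster.
#' @param n_sidefx_per_drug Side-effect draws per drug.
#' @param investigational_rate Rate of non-approved association rows
#'   (exercises the status filter).
#' @param seed Integer seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_drugs = 60L, n_diseases = 25L,
                             n_clusters = 4L,
                             vocab = list(
                               chemical_substructure = 48L,
                               target_protein = 28L, protein_domain = 18L,
                               side_effect = 40L, atc_code = 12L,
                               gene = 32L, disease_class = 8L,
                               disease_type = 8L, semantic_type = 8L
                             ),
                             p_in = 0.25, p_out = 0.04,
                             treat_prob_in = 0.5, treat_prob_out = 0.05,
                             sidefx_disease_overlap = 0.5,
                             sidefx_cross_bias = 0.8,
                             n_sidefx_per_drug = 6L,
                             investigational_rate = 0.03,
                             seed = 1L) {
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop("need 0 <= p_out < p_in <= 1")
  }
  if (sidefx_disease_overlap <= 0 || sidefx_disease_overlap > 1) {
    stop("sidefx_disease_overlap must be in (0, 1]: without overlap the ",
         "adverse-reaction rule can produce no negatives")
  }
  if (n_clusters < 2L) stop("need at least 2 clusters")
  structure(
    list(n_drugs = as.integer(n_drugs), n_diseases = as.integer(n_diseases),
         n_clusters = as.integer(n_clusters), vocab = vocab,
         p_in = p_in, p_out = p_out,
         treat_prob_in = treat_prob_in, treat_prob_out = treat_prob_out,
         sidefx_disease_overlap = sidefx_disease_overlap,
         sidefx_cross_bias = sidefx_cross_bias,
         n_sidefx_per_drug = as.integer(n_sidefx_per_drug),
         investigational_rate = investigational_rate,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Matched no-signal variant of a synthetic configuration
#'
#' Removes the planted association signal while keeping the overall
#' positive rate comparable: both treatment rates are set to the
#' cluster-averaged rate of the input configuration, and the side-effect
#' cross-cluster bias is set to zero (a biased negative rule alone would
#' correlate labels with clusters even when treatments do not).
#'
#' @param config A [synthetic_config()].
#' @return The null configuration.
#' @export
null_synthetic_config <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  k <- config$n_clusters
  rate <- config$treat_prob_in / k + config$treat_prob_out * (1 - 1 / k)
  config$treat_prob_in <- rate
  config$treat_prob_out <- rate
  config$sidefx_cross_bias <- 0
  config
}

# cluster-preferential bipartite edges: one Bernoulli per (entity, item)
.cluster_edges <- function(ent_ids, ent_cl, item_ids, item_cl, p_in, p_out) {
  pm <- outer(ent_cl, item_cl, function(a, b) ifelse(a == b, p_in, p_out))
  hit <- which(matrix(stats::runif(length(pm)), nrow(pm)) < pm,
               arr.ind = TRUE)
  data.frame(head_id = ent_ids[hit[, 1L]], tail_id = item_ids[hit[, 2L]],
             stringsAsFactors = FALSE)
}

#' Generate a synthetic knowledge graph and association tables
#'
#' Emits schema-valid node/edge tables plus association and side-effect
#' tables in the exact dialect consumed by [build_kg()],
#' [build_positive_set()] and [build_negative_set()], together with the
#' generating ground truth (cluster assignments and the association
#' matrix). Deterministic given the configuration seed.
#'
#' @param config A [synthetic_config()].
#' @return list with `nodes`, `edges`, `associations`, `side_effects`
#'   (data.frames) and `truth` (list: `drug_clusters`, `disease_clusters`,
#'   `pairs` data.frame with `drug`, `disease`, `same_cluster`,
#'   `associated`).
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  K <- cfg$n_clusters
  withr::with_seed(cfg$seed, {
    drugs <- sprintf("r%03d", seq_len(cfg$n_drugs))
    dis <- sprintf("p%03d", seq_len(cfg$n_diseases))
    drug_cl <- sample(rep_len(seq_len(K), cfg$n_drugs))
    dis_cl <- sample(rep_len(seq_len(K), cfg$n_diseases))

    mk_vocab <- function(prefix, n) {
      list(ids = sprintf("%s%03d", prefix, seq_len(n)),
           cl = rep_len(seq_len(K), n))
    }
    sub <- mk_vocab("c", cfg$vocab$chemical_substructure)
    tgt <- mk_vocab("t", cfg$vocab$target_protein)
    dom <- mk_vocab("d", cfg$vocab$protein_domain)
    atc <- mk_vocab("a", cfg$vocab$atc_code)
    gen <- mk_vocab("g", cfg$vocab$gene)
    cls <- mk_vocab("mc", cfg$vocab$disease_class)
    typ <- mk_vocab("ty", cfg$vocab$disease_type)
    sem <- mk_vocab("st", cfg$vocab$semantic_type)

    # side-effect vocabulary: a slice is identity-mapped to disease ids
    n_map <- min(floor(cfg$sidefx_disease_overlap * cfg$vocab$side_effect),
                 cfg$n_diseases)
    if (n_map < 1L) stop("side-effect/disease overlap is empty")
    mapped <- sample(dis, n_map)
    generic <- sprintf("s%03d", seq_len(max(0L,
                                            cfg$vocab$side_effect - n_map)))
    sfx_ids <- c(mapped, generic)
    sfx_cl <- c(dis_cl[match(mapped, dis)],
                rep_len(seq_len(K), length(generic)))

    edge <- function(df, relation) {
      if (nrow(df) == 0L) return(NULL)
      data.frame(head_id = df$head_id, relation = relation,
                 tail_id = df$tail_id, stringsAsFactors = FALSE)
    }

    edges <- list(
      edge(.cluster_edges(drugs, drug_cl, sub$ids, sub$cl,
                          cfg$p_in, cfg$p_out), "has_chemical_substructure"),
      edge(.cluster_edges(drugs, drug_cl, tgt$ids, tgt$cl,
                          cfg$p_in, cfg$p_out), "has_target"),
      edge(.cluster_edges(dis, dis_cl, gen$ids, gen$cl,
                          cfg$p_in, cfg$p_out), "has_gene"),
      edge(.cluster_edges(gen$ids, gen$cl, tgt$ids, tgt$cl,
                          cfg$p_in, cfg$p_out), "has_encoded")
    )

    # each target carries one or two domains, cluster-preferred
    n_dom <- 1L + stats::rbinom(length(tgt$ids), 1L, 0.5)
    td <- do.call(rbind, lapply(seq_along(tgt$ids), function(i) {
      own <- dom$ids[dom$cl == tgt$cl[i]]
      pool <- if (stats::runif(1) < 0.8 && length(own)) own else dom$ids
      data.frame(head_id = tgt$ids[i],
                 tail_id = sample(pool, min(n_dom[i], length(pool))),
                 stringsAsFactors = FALSE)
    }))
    edges <- c(edges, list(edge(td, "has_domain_target")))

    # one or two ATC codes per drug
    pick_pref <- function(cl, voc) {
      own <- voc$ids[voc$cl == cl]
      if (stats::runif(1) < 0.8 && length(own)) sample(own, 1L) else
        sample(voc$ids, 1L)
    }
    at <- do.call(rbind, lapply(seq_along(drugs), function(i) {
      codes <- unique(c(pick_pref(drug_cl[i], atc),
                        if (stats::runif(1) < 0.3)
                          pick_pref(drug_cl[i], atc)))
      data.frame(head_id = drugs[i], tail_id = codes,
                 stringsAsFactors = FALSE)
    }))
    edges <- c(edges, list(edge(at, "has_ATC_code")))

    # one class/type/semantic per disease, cluster-preferred
    for (voc_rel in list(list(cls, "has_class"), list(typ, "has_type"),
                         list(sem, "has_semantic_type"))) {
      vv <- do.call(rbind, lapply(seq_along(dis), function(i) {
        data.frame(head_id = dis[i],
                   tail_id = pick_pref(dis_cl[i], voc_rel[[1L]]),
                   stringsAsFactors = FALSE)
      }))
      edges <- c(edges, list(edge(vv, voc_rel[[2L]])))
    }

    # within-cluster interaction networks (no self-loops, upper triangle)
    pair_net <- function(ids, cl) {
      n <- length(ids)
      ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      pp <- ifelse(cl[ut[, 1L]] == cl[ut[, 2L]], cfg$p_in, cfg$p_out)
      hit <- stats::runif(nrow(ut)) < pp
      data.frame(head_id = ids[ut[hit, 1L]], tail_id = ids[ut[hit, 2L]],
                 stringsAsFactors = FALSE)
    }
    edges <- c(edges, list(
      edge(pair_net(tgt$ids, tgt$cl), "has_interaction"),
      edge(pair_net(gen$ids, gen$cl), "has_gene_interaction")
    ))

    # therapeutic associations: cluster-dependent Bernoulli
    same <- outer(drug_cl, dis_cl, "==")
    pmat <- ifelse(same, cfg$treat_prob_in, cfg$treat_prob_out)
    assoc_hit <- matrix(stats::runif(length(pmat)), nrow(pmat)) < pmat
    hit <- which(assoc_hit, arr.ind = TRUE)
    associations <- data.frame(
      drug_id = drugs[hit[, 1L]], disease_id = dis[hit[, 2L]],
      status = "approved", stringsAsFactors = FALSE
    )
    inv <- which(!assoc_hit &
                   matrix(stats::runif(length(pmat)), nrow(pmat)) <
                     cfg$investigational_rate, arr.ind = TRUE)
    if (nrow(inv)) {
      associations <- rbind(associations, data.frame(
        drug_id = drugs[inv[, 1L]], disease_id = dis[inv[, 2L]],
        status = "investigational", stringsAsFactors = FALSE
      ))
    }
    edges <- c(edges, list(edge(
      data.frame(head_id = drugs[hit[, 1L]], tail_id = dis[hit[, 2L]],
                 stringsAsFactors = FALSE),
      "has_treatment"
    )))

    # side effects: biased towards disease-mapped terms of other clusters
    cross_of <- lapply(seq_len(K), function(c0) {
      mapped[dis_cl[match(mapped, dis)] != c0]
    })
    side_effects <- do.call(rbind, lapply(seq_along(drugs), function(i) {
      draws <- vapply(seq_len(cfg$n_sidefx_per_drug), function(j) {
        pool <- cross_of[[drug_cl[i]]]
        if (stats::runif(1) < cfg$sidefx_cross_bias && length(pool)) {
          sample(pool, 1L)
        } else {
          sample(sfx_ids, 1L)
        }
      }, character(1))
      data.frame(drug_id = drugs[i], term_id = unique(draws),
                 stringsAsFactors = FALSE)
    }))
    edges <- c(edges, list(edge(
      data.frame(head_id = side_effects$drug_id,
                 tail_id = side_effects$term_id, stringsAsFactors = FALSE),
      "has_side_effect"
    )))

    nodes <- rbind(
      data.frame(node_id = drugs, node_type = "drug"),
      data.frame(node_id = dis, node_type = "disease"),
      data.frame(node_id = sub$ids, node_type = "chemical_substructure"),
      data.frame(node_id = tgt$ids, node_type = "target_protein"),
      data.frame(node_id = dom$ids, node_type = "protein_domain"),
      data.frame(node_id = sfx_ids, node_type = "side_effect"),
      data.frame(node_id = atc$ids, node_type = "atc_code"),
      data.frame(node_id = gen$ids, node_type = "gene"),
      data.frame(node_id = cls$ids, node_type = "disease_class"),
      data.frame(node_id = typ$ids, node_type = "disease_type"),
      data.frame(node_id = sem$ids, node_type = "semantic_type")
    )
    edges <- unique(do.call(rbind, edges))
    rownames(edges) <- NULL

    truth_pairs <- data.frame(
      drug = rep(drugs, times = cfg$n_diseases),
      disease = rep(dis, each = cfg$n_drugs),
      same_cluster = as.vector(same),
      associated = as.vector(assoc_hit),
      stringsAsFactors = FALSE
    )
    list(
      nodes = nodes, edges = edges, associations = associations,
      side_effects = side_effects,
      truth = list(
        drug_clusters = stats::setNames(drug_cl, drugs),
        disease_clusters = stats::setNames(dis_cl, dis),
        pairs = truth_pairs
      )
    )
  })
}

#' Linearly separable drug-disease feature fixture
#'
#' Builds `n/2` positive and `n/2` negative pairs whose drug and disease
#' vectors differ by a class-dependent offset: positives differ by at
#' most `margin / 4` per coordinate, negatives by at least `margin`, so
#' the classes are linearly separable in the absolute-difference space
#' any one-layer classifier sees after the merge.
#'
#' @param n Even number of pairs.
#' @param dim Vector dimension per entity.
#' @param margin Positive separation margin.
#' @param seed Integer seed.
#' @return A `feature_block` with exactly balanced labels.
#' @export
make_separable_fixture <- function(n, dim, margin, seed = 1L) {
  if (margin <= 0) stop("margin must be > 0")
  if (n %% 2L != 0L) stop("n must be even")
  half <- n %/% 2L
  withr::with_seed(seed, {
    r <- matrix(stats::rnorm(n * dim), n, dim)
    close_off <- matrix(stats::runif(half * dim, -margin / 4, margin / 4),
                        half, dim)
    far_off <- matrix(margin + stats::runif(half * dim, 0, margin / 2),
                      half, dim)
    p <- rbind(r[seq_len(half), ] + close_off,
               r[half + seq_len(half), ] + far_off)
  })
  structure(
    list(x = cbind(r, p), y = c(rep(1L, half), rep(0L, half)), pairs = NULL),
    class = "feature_block"
  )
}

#' Write synthetic tables to a directory
#'
#' Emits `nodes.tsv`, `edges.tsv`, `associations.tsv`,
#' `side_effects.tsv` and `truth_pairs.tsv` in the dialects the rest of
#' the package consumes.
#'
#' @param synth Output of [generate_synthetic()].
#' @param dir Destination directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_synthetic <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  w(synth$nodes, "nodes.tsv")
  w(synth$edges, "edges.tsv")
  w(synth$associations, "associations.tsv")
  w(synth$side_effects, "side_effects.tsv")
  w(synth$truth$pairs, "truth_pairs.tsv")
  invisible(dir)
}
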