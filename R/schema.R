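#' Node types of the drug-disease knowledge graph
#'
#' The graph schema distinguishes eleven node types: the drug and disease
#' entities themselves plus five drug feature types (chemical substructures
#' from fingerprints, target proteins, protein domains, side effects, ATC
#' codes) and four disease feature types (disease type, MeSH-style class,
#' associated genes, UMLS-style semantic type).
#'
#' @return Character vector of the 11 node type names.
#' @export
node_types <- function() {
  c(
    "drug", "chemical_substructure", "target_protein", "protein_domain",
    "side_effect", "atc_code",
    "disease", "disease_type", "disease_class", "gene", "semantic_type"
  )
}

#' Relation types and their signatures
#'
#' Returns the fixed table of the 14 typed relations: each relation has a
#' head (domain) and tail (range) node type and belongs to one of three
#' groups — `intra_drug` (7 relations among drug features), `intra_disease`
#' (5 among disease features) and `inter` (2 bridging drugs and diseases:
#' therapeutic treatment and gene-encodes-target).
#'
#' @return A data.frame with columns `relation`, `head_type`, `tail_type`,
#'   `group`.
#' @export
relation_types <- function() {
  data.frame(
    relation = c(
      "has_chemical_substructure", "has_target", "has_domain",
      "has_side_effect", "has_ATC_code", "has_interaction",
      "has_domain_target",
      "has_type", "has_class", "has_gene", "has_semantic_type",
      "has_gene_interaction",
      "has_treatment", "has_encoded"
    ),
    head_type = c(
      "drug", "drug", "drug", "drug", "drug",
      "target_protein", "target_protein",
      "disease", "disease", "disease", "disease", "gene",
      "drug", "gene"
    ),
    tail_type = c(
      "chemical_substructure", "target_protein", "protein_domain",
      "side_effect", "atc_code", "target_protein", "protein_domain",
      "disease_type", "disease_class", "gene", "semantic_type", "gene",
      "disease", "target_protein"
    ),
    group = c(
      rep("intra_drug", 7), rep("intra_disease", 5), rep("inter", 2)
    ),
    stringsAsFactors = FALSE
  )
}

# relations for which self-loops are forbidden (symmetric interaction types)
.symmetric_relations <- c("has_interaction", "has_gene_interaction")

#' Relation subset of a graph version
#'
#' Four nested versions of the graph schema are supported. `V2` is the
#' baseline feature set (drug substructure/target/domain/side-effect/ATC,
#' disease type/class/gene/semantic, and treatment edges). `V3` adds the
#' intra-feature interaction relations (protein-protein, target-domain,
#' gene-gene), `V4` adds the gene-encodes-target inter relation, and `V1`
#' is the full schema (union of V3 and V4).
#'
#' @param version One of `"V1"`, `"V2"`, `"V3"`, `"V4"`.
#' @return Character vector of relation names allowed in that version.
#' @export
version_relations <- function(version = c("V1", "V2", "V3", "V4")) {
  version <- match.arg(version)
  v2 <- c(
    "has_chemical_substructure", "has_target", "has_domain",
    "has_side_effect", "has_ATC_code",
    "has_type", "has_class", "has_gene", "has_semantic_type",
    "has_treatment"
  )
  switch(version,
    V1 = relation_types()$relation,
    V2 = v2,
    V3 = c(v2, "has_interaction", "has_domain_target", "has_gene_interaction"),
    V4 = c(v2, "has_encoded")
  )
}

# namespaced node id "type:local"
.ns <- function(type, local) paste(type, local, sep = ":")

.local_id <- function(id) sub("^[^:]+:", "", id)
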