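#' Build a typed drug-disease knowledge graph from tabular input
#'
#' Assembles a validated knowledge graph from a node table and an edge
#' table. Node identifiers are namespaced internally as `"type:local_id"`
#' so that vocabularies of different node types cannot collide (a side
#' effect term may share its local identifier with a disease). Edge
#' endpoints are resolved against the node table using the relation's type
#' signature, duplicate rows are collapsed, and the triplet set is
#' restricted to the relations allowed by `version`.
#'
#' @param nodes data.frame with columns `node_id`, `node_type`.
#' @param edges data.frame with columns `head_id`, `relation`, `tail_id`.
#' @param version Graph version tag; see [version_relations()].
#' @return An object of class `ddkg`: a list with `nodes` (named character
#'   vector mapping namespaced id to node type), `triplets` (data.frame
#'   `head`, `relation`, `tail` of namespaced ids) and `version`.
#' @examples
#' tabs <- list(
#'   nodes = data.frame(node_id = c("r1", "p1"),
#'                      node_type = c("drug", "disease")),
#'   edges = data.frame(head_id = "r1", relation = "has_treatment",
#'                      tail_id = "p1")
#' )
#' kg <- build_kg(tabs$nodes, tabs$edges, version = "V1")
#' @export
build_kg <- function(nodes, edges, version = c("V1", "V2", "V3", "V4")) {
  version <- match.arg(version)
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  if (nrow(nodes) == 0L || nrow(edges) == 0L) {
    stop("node and edge tables must be non-empty")
  }
  need_n <- c("node_id", "node_type")
  need_e <- c("head_id", "relation", "tail_id")
  if (!all(need_n %in% names(nodes))) {
    stop("node table must have columns: ", paste(need_n, collapse = ", "))
  }
  if (!all(need_e %in% names(edges))) {
    stop("edge table must have columns: ", paste(need_e, collapse = ", "))
  }
  nodes <- unique(nodes[, need_n])
  bad_type <- setdiff(nodes$node_type, node_types())
  if (length(bad_type)) {
    stop("unknown node type(s): ", paste(bad_type, collapse = ", "))
  }
  sig <- relation_types()
  bad_rel <- setdiff(edges$relation, sig$relation)
  if (length(bad_rel)) {
    stop("unknown relation type(s): ", paste(bad_rel, collapse = ", "))
  }

  node_key <- paste(nodes$node_type, nodes$node_id, sep = ":")
  node_map <- stats::setNames(nodes$node_type, node_key)

  i <- match(edges$relation, sig$relation)
  ht <- sig$head_type[i]
  tt <- sig$tail_type[i]
  head_ns <- .ns(ht, edges$head_id)
  tail_ns <- .ns(tt, edges$tail_id)
  miss_h <- !(head_ns %in% node_key)
  miss_t <- !(tail_ns %in% node_key)
  if (any(miss_h | miss_t)) {
    bad <- which(miss_h | miss_t)
    stop(
      "type-signature mismatch or missing node for edge row(s): ",
      paste(utils::head(sprintf(
        "(%s, %s, %s)", edges$head_id[bad], edges$relation[bad],
        edges$tail_id[bad]
      ), 10L), collapse = "; ")
    )
  }
  self_loop <- edges$relation %in% .symmetric_relations & head_ns == tail_ns
  if (any(self_loop)) {
    bad <- which(self_loop)
    stop(
      "self-loop not allowed for interaction relation(s), edge row(s): ",
      paste(sprintf("(%s, %s, %s)", edges$head_id[bad], edges$relation[bad],
                    edges$tail_id[bad]), collapse = "; ")
    )
  }

  triplets <- unique(data.frame(
    head = head_ns, relation = edges$relation, tail = tail_ns,
    stringsAsFactors = FALSE
  ))
  keep <- triplets$relation %in% version_relations(version)
  triplets <- triplets[keep, , drop = FALSE]
  rownames(triplets) <- NULL

  structure(
    list(nodes = node_map, triplets = triplets, version = version),
    class = "ddkg"
  )
}

#' @export
print.ddkg <- function(x, ...) {
  cat(sprintf(
    "<ddkg %s> %d nodes (%d types), %d triplets (%d relation types)\n",
    x$version, length(x$nodes), length(unique(x$nodes)),
    nrow(x$triplets), length(unique(x$triplets$relation))
  ))
  invisible(x)
}

#' Materialize drug-to-domain edges through targets
#'
#' A drug acquires a `has_domain` edge to every protein domain of its
#' target proteins: for each pair of triplets (r, has_target, t) and
#' (t, has_domain_target, d) the edge (r, has_domain, d) is added. Input
#' tables may also list drug-domain edges directly; the result is the set
#' union, and the operation is idempotent.
#'
#' @param kg A `ddkg` object.
#' @return The graph with derived `has_domain` triplets added.
#' @export
derive_drug_domain_edges <- function(kg) {
  stopifnot(inherits(kg, "ddkg"))
  if (!("has_domain" %in% version_relations(kg$version))) {
    return(kg)
  }
  tg <- kg$triplets[kg$triplets$relation == "has_target", , drop = FALSE]
  td <- kg$triplets[kg$triplets$relation == "has_domain_target", , drop = FALSE]
  if (nrow(tg) == 0L || nrow(td) == 0L) {
    return(kg)
  }
  joined <- merge(
    tg[, c("head", "tail")], td[, c("head", "tail")],
    by.x = "tail", by.y = "head", suffixes = c("_drug", "_dom")
  )
  if (nrow(joined) == 0L) {
    return(kg)
  }
  new_trip <- data.frame(
    head = joined$head, relation = "has_domain", tail = joined$tail_dom,
    stringsAsFactors = FALSE
  )
  kg$triplets <- unique(rbind(kg$triplets, new_trip))
  rownames(kg$triplets) <- NULL
  kg
}

#' Remove association edges that would leak evaluation pairs
#'
#' Deletes, for every listed drug-disease pair, the `has_treatment` triplet
#' (if present) and the `has_side_effect` triplet whose side-effect term is
#' identity-mapped to the disease (side effects and diseases share a
#' normalized identifier space, so a pair used as an adverse-reaction
#' negative is recognizable by its local identifier). Used to keep held-out
#' pairs out of the embedding corpus. The node set is never changed.
#'
#' @param kg A `ddkg` object.
#' @param pairs data.frame with columns `drug`, `disease` (local ids).
#' @return The graph without the leaking triplets.
#' @export
remove_treatment_edges <- function(kg, pairs) {
  stopifnot(inherits(kg, "ddkg"))
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(kg)
  }
  stopifnot(all(c("drug", "disease") %in% names(pairs)))
  drug_ns <- .ns("drug", pairs$drug)
  dis_ns <- .ns("disease", pairs$disease)
  unknown <- !(drug_ns %in% names(kg$nodes))
  if (any(unknown)) {
    stop("unknown drug node(s): ", paste(pairs$drug[unknown], collapse = ", "))
  }
  unknown_d <- !(dis_ns %in% names(kg$nodes))
  if (any(unknown_d)) {
    stop("unknown disease node(s): ",
         paste(pairs$disease[unknown_d], collapse = ", "))
  }
  key_treat <- paste(drug_ns, dis_ns)
  sidefx_ns <- .ns("side_effect", pairs$disease)
  key_side <- paste(drug_ns, sidefx_ns)
  tr <- kg$triplets
  drop <- (tr$relation == "has_treatment" &
             paste(tr$head, tr$tail) %in% key_treat) |
    (tr$relation == "has_side_effect" &
       paste(tr$head, tr$tail) %in% key_side)
  kg$triplets <- tr[!drop, , drop = FALSE]
  rownames(kg$triplets) <- NULL
  kg
}

#' Validate a knowledge graph against the schema
#'
#' Checks every triplet against the fixed relation signature table,
#' flags endpoints missing from the node set, duplicate triplets,
#' self-loops on interaction relations, and relations outside the graph
#' version's allowed set. Violations are returned as data, not raised.
#'
#' @param kg A `ddkg` object.
#' @return A list of class `ddkg_validation` with `errors` (data.frame
#'   `head`, `relation`, `tail`, `rule`), `node_type_counts` and
#'   `relation_counts`.
#' @export
validate_kg <- function(kg) {
  stopifnot(inherits(kg, "ddkg"))
  sig <- relation_types()
  tr <- kg$triplets
  errs <- list()
  add_err <- function(rows, rule) {
    if (length(rows)) {
      errs[[length(errs) + 1L]] <<- data.frame(
        head = tr$head[rows], relation = tr$relation[rows],
        tail = tr$tail[rows], rule = rule, stringsAsFactors = FALSE
      )
    }
  }
  if (nrow(tr)) {
    i <- match(tr$relation, sig$relation)
    add_err(which(is.na(i)), "unknown_relation")
    known <- which(!is.na(i))
    h_type <- kg$nodes[tr$head]
    t_type <- kg$nodes[tr$tail]
    add_err(which(is.na(h_type) | is.na(t_type)), "missing_node")
    ok <- known[!is.na(h_type[known]) & !is.na(t_type[known])]
    mism <- ok[h_type[ok] != sig$head_type[i[ok]] |
                 t_type[ok] != sig$tail_type[i[ok]]]
    add_err(mism, "signature_mismatch")
    key <- paste(tr$head, tr$relation, tr$tail)
    add_err(which(duplicated(key)), "duplicate_triplet")
    add_err(
      which(tr$relation %in% .symmetric_relations & tr$head == tr$tail),
      "self_loop"
    )
    add_err(
      which(!(tr$relation %in% version_relations(kg$version))),
      "relation_outside_version"
    )
  }
  errors <- if (length(errs)) {
    do.call(rbind, errs)
  } else {
    data.frame(head = character(), relation = character(),
               tail = character(), rule = character(),
               stringsAsFactors = FALSE)
  }
  structure(
    list(
      errors = errors,
      node_type_counts = table(kg$nodes),
      relation_counts = table(factor(tr$relation, levels = sig$relation))
    ),
    class = "ddkg_validation"
  )
}

#' @export
print.ddkg_validation <- function(x, ...) {
  cat(sprintf("<ddkg validation> %d error(s)\n", nrow(x$errors)))
  if (nrow(x$errors)) print(utils::head(x$errors, 20L))
  invisible(x)
}

#' Expand ATC codes into their hierarchy levels
#'
#' ATC codes are hierarchical (anatomical group, therapeutic subgroup,
#' pharmacological subgroup, chemical subgroup, substance, at string
#' prefixes of length 1, 3, 4, 5 and 7). Each `has_ATC_code` edge is
#' replaced by one edge per hierarchy level present in the code, and the
#' prefix nodes are appended to the node table.
#'
#' @param nodes,edges Input tables as for [build_kg()].
#' @param levels Integer prefix lengths defining the hierarchy.
#' @return list with expanded `nodes` and `edges` tables.
#' @export
expand_atc_codes <- function(nodes, edges, levels = c(1L, 3L, 4L, 5L, 7L)) {
  is_atc <- edges$relation == "has_ATC_code"
  if (!any(is_atc)) {
    return(list(nodes = nodes, edges = edges))
  }
  atc <- edges[is_atc, , drop = FALSE]
  expanded <- do.call(rbind, lapply(seq_len(nrow(atc)), function(k) {
    code <- atc$tail_id[k]
    lv <- levels[levels <= nchar(code)]
    data.frame(
      head_id = atc$head_id[k], relation = "has_ATC_code",
      tail_id = unique(substring(code, 1L, lv)), stringsAsFactors = FALSE
    )
  }))
  new_nodes <- data.frame(
    node_id = unique(expanded$tail_id), node_type = "atc_code",
    stringsAsFactors = FALSE
  )
  list(
    nodes = unique(rbind(nodes[, c("node_id", "node_type")], new_nodes)),
    edges = unique(rbind(edges[!is_atc, , drop = FALSE], expanded))
  )
}

#' Re-export a knowledge graph as node and edge tables
#'
#' Inverse of [build_kg()]: local identifiers are recovered by stripping
#' the type namespace.
#'
#' @param kg A `ddkg` object.
#' @return list with `nodes` and `edges` data.frames in the input dialect.
#' @export
kg_to_tables <- function(kg) {
  stopifnot(inherits(kg, "ddkg"))
  nodes <- data.frame(
    node_id = .local_id(names(kg$nodes)), node_type = unname(kg$nodes),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    head_id = .local_id(kg$triplets$head),
    relation = kg$triplets$relation,
    tail_id = .local_id(kg$triplets$tail),
    stringsAsFactors = FALSE
  )
  list(nodes = nodes, edges = edges)
}

#' Read node/edge tables from TSV
#'
#' @param nodes_path,edges_path Paths to UTF-8 tab-separated files with
#'   header rows (`node_id`, `node_type`) and (`head_id`, `relation`,
#'   `tail_id`).
#' @return list with `nodes` and `edges` data.frames.
#' @export
read_kg_tables <- function(nodes_path, edges_path) {
  list(
    nodes = utils::read.delim(nodes_path, stringsAsFactors = FALSE,
                              colClasses = "character"),
    edges = utils::read.delim(edges_path, stringsAsFactors = FALSE,
                              colClasses = "character")
  )
}

#' Write a knowledge graph to TSV
#'
#' @param kg A `ddkg` object.
#' @param edges_path Destination for the canonical edge list.
#' @param nodes_path Optional destination for the node table.
#' @return Invisibly, the edge path.
#' @export
write_kg <- function(kg, edges_path, nodes_path = NULL) {
  tabs <- kg_to_tables(kg)
  utils::write.table(tabs$edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(nodes_path)) {
    utils::write.table(tabs$nodes, nodes_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(edges_path)
}

#' Write a validation report as JSON
#'
#' @param report A `ddkg_validation` object.
#' @param path Destination file.
#' @return Invisibly, the path.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "ddkg_validation"))
  jsonlite::write_json(
    list(
      n_errors = nrow(report$errors),
      errors = report$errors,
      node_type_counts = as.list(report$node_type_counts),
      relation_counts = as.list(report$relation_counts)
    ),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
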