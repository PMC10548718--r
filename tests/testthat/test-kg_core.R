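trip_key <- function(kg) {
  sort(paste(kg$triplets$head, kg$triplets$relation, kg$triplets$tail))
}

test_that("schema constants match the graph definition", {
  expect_length(node_types(), 11L)
  expect_false(anyDuplicated(node_types()) > 0L)
  rt <- relation_types()
  expect_equal(nrow(rt), 14L)
  expect_equal(unname(table(rt$group)[c("intra_drug", "intra_disease",
                                        "inter")]),
               c(7L, 5L, 2L), ignore_attr = TRUE)
  expect_length(version_relations("V1"), 14L)
  expect_length(version_relations("V2"), 10L)
  expect_length(version_relations("V3"), 13L)
  expect_length(version_relations("V4"), 11L)
})

test_that("build_kg assembles and version-restricts the toy graph", {
  tt <- toy_tables()
  kg <- build_kg(tt$nodes, tt$edges, "V1")
  expect_length(kg$nodes, 12L)
  expect_equal(nrow(kg$triplets), 13L)
  kg2 <- build_kg(tt$nodes, tt$edges, "V2")
  expect_equal(nrow(kg2$triplets), 11L)
  expect_false(any(c("has_domain_target", "has_encoded") %in%
                     kg2$triplets$relation))
  # duplicated input rows collapse
  kg3 <- build_kg(tt$nodes, rbind(tt$edges, tt$edges[1, ]), "V1")
  expect_equal(nrow(kg3$triplets), 13L)
})

test_that("build_kg rejects schema violations", {
  tt <- toy_tables()
  bad <- rbind(tt$edges,
               data.frame(head_id = "p1", relation = "has_target",
                          tail_id = "t1"))
  expect_error(build_kg(tt$nodes, bad, "V1"), "mismatch|missing")
  bad2 <- tt$edges
  bad2$relation[1] <- "has_banana"
  expect_error(build_kg(tt$nodes, bad2, "V1"), "unknown relation")
  badn <- tt$nodes
  badn$node_type[1] <- "nonsense"
  expect_error(build_kg(badn, tt$edges, "V1"), "unknown node type")
  loop <- rbind(tt$edges,
                data.frame(head_id = "t1", relation = "has_interaction",
                           tail_id = "t1"))
  expect_error(build_kg(tt$nodes, loop, "V1"), "self-loop")
})

test_that("build_kg is invariant to input row order", {
  tt <- toy_tables()
  kg_a <- build_kg(tt$nodes, tt$edges, "V1")
  perm <- withr::with_seed(42, sample.int(nrow(tt$edges)))
  kg_b <- build_kg(tt$nodes[sample(nrow(tt$nodes)), ],
                   tt$edges[perm, ], "V1")
  expect_equal(trip_key(kg_a), trip_key(kg_b))
})

test_that("version lattice holds on synthetic tables: V2 = V3 n V4, V1 = V3 u V4", {
  synth <- generate_synthetic(small_synth_config(seed = 3))
  kgs <- lapply(c("V1", "V2", "V3", "V4"), function(v) {
    build_kg(synth$nodes, synth$edges, v)
  })
  names(kgs) <- c("V1", "V2", "V3", "V4")
  expect_equal(trip_key(kgs$V2),
               intersect(trip_key(kgs$V3), trip_key(kgs$V4)))
  expect_equal(trip_key(kgs$V1),
               sort(union(trip_key(kgs$V3), trip_key(kgs$V4))))
})

test_that("derive_drug_domain_edges composes target and domain edges, idempotently", {
  tt <- toy_tables()
  kg <- build_kg(tt$nodes, tt$edges[tt$edges$relation != "has_domain", ],
                 "V1")
  kg2 <- derive_drug_domain_edges(kg)
  expect_true(any(kg2$triplets$relation == "has_domain" &
                    kg2$triplets$head == "drug:r1" &
                    kg2$triplets$tail == "protein_domain:d1"))
  expect_equal(trip_key(derive_drug_domain_edges(kg2)), trip_key(kg2))
  # no has_target edges: unchanged
  kg0 <- build_kg(tt$nodes,
                  tt$edges[!tt$edges$relation %in%
                             c("has_target", "has_domain"), ], "V1")
  expect_equal(trip_key(derive_drug_domain_edges(kg0)), trip_key(kg0))
})

test_that("two targets sharing one domain yield exactly one derived edge", {
  nodes <- data.frame(
    node_id = c("r1", "t1", "t2", "d1"),
    node_type = c("drug", "target_protein", "target_protein",
                  "protein_domain")
  )
  edges <- data.frame(
    head_id = c("r1", "r1", "t1", "t2"),
    relation = c("has_target", "has_target", "has_domain_target",
                 "has_domain_target"),
    tail_id = c("t1", "t2", "d1", "d1")
  )
  kg <- derive_drug_domain_edges(build_kg(nodes, edges, "V1"))
  expect_equal(sum(kg$triplets$relation == "has_domain"), 1L)
})

test_that("remove_treatment_edges drops treatment and identity side-effect leaks", {
  tt <- toy_tables()
  # add a side-effect term identity-mapped to a second disease
  tt$nodes <- rbind(tt$nodes,
                    data.frame(node_id = c("p2", "p2"),
                               node_type = c("disease", "side_effect")))
  tt$edges <- rbind(tt$edges,
                    data.frame(head_id = "r1", relation = "has_side_effect",
                               tail_id = "p2"))
  kg <- build_kg(tt$nodes, tt$edges, "V1")

  out <- remove_treatment_edges(kg, data.frame(drug = "r1", disease = "p1"))
  expect_false(any(out$triplets$relation == "has_treatment"))
  expect_equal(names(out$nodes), names(kg$nodes))

  out2 <- remove_treatment_edges(kg, data.frame(drug = "r1",
                                                disease = "p2"))
  expect_false(any(out2$triplets$relation == "has_side_effect" &
                     out2$triplets$tail == "side_effect:p2"))
  # the unrelated side effect s1 survives
  expect_true(any(out2$triplets$tail == "side_effect:s1"))

  expect_equal(trip_key(remove_treatment_edges(kg, data.frame(
    drug = character(), disease = character()))), trip_key(kg))
  expect_error(remove_treatment_edges(kg, data.frame(drug = "nope",
                                                     disease = "p1")),
               "unknown drug")
})

test_that("validate_kg reports violations as data", {
  tt <- toy_tables()
  kg <- build_kg(tt$nodes, tt$edges, "V1")
  rep0 <- validate_kg(kg)
  expect_equal(nrow(rep0$errors), 0L)
  expect_equal(unname(rep0$relation_counts["has_chemical_substructure"]), 2L,
               ignore_attr = TRUE)

  kg_bad <- kg
  kg_bad$triplets <- rbind(
    kg_bad$triplets,
    data.frame(head = "target_protein:t1", relation = "has_interaction",
               tail = "target_protein:t1"),
    data.frame(head = "drug:ghost", relation = "has_target",
               tail = "target_protein:t1"),
    kg_bad$triplets[1, ]
  )
  rep1 <- validate_kg(kg_bad)
  expect_true("self_loop" %in% rep1$errors$rule)
  expect_true("missing_node" %in% rep1$errors$rule)
  expect_true("duplicate_triplet" %in% rep1$errors$rule)
})

test_that("ATC codes expand one edge per hierarchy level", {
  tt <- toy_tables()
  tt$edges$tail_id[tt$edges$relation == "has_ATC_code"] <- "A10BA02"
  ex <- expand_atc_codes(tt$nodes, tt$edges)
  atc <- ex$edges[ex$edges$relation == "has_ATC_code", ]
  expect_equal(sort(atc$tail_id), c("A", "A10", "A10B", "A10BA", "A10BA02"))
  expect_true(all(atc$tail_id %in%
                    ex$nodes$node_id[ex$nodes$node_type == "atc_code"]))
  kg <- build_kg(ex$nodes, ex$edges, "V1")
  expect_equal(nrow(validate_kg(kg)$errors), 0L)
})

test_that("graph round-trips through tables and TSV files", {
  tt <- toy_tables()
  kg <- build_kg(tt$nodes, tt$edges, "V1")
  dir <- withr::local_tempdir()
  write_kg(kg, file.path(dir, "edges.tsv"), file.path(dir, "nodes.tsv"))
  tabs <- read_kg_tables(file.path(dir, "nodes.tsv"),
                         file.path(dir, "edges.tsv"))
  kg2 <- build_kg(tabs$nodes, tabs$edges, "V1")
  expect_equal(trip_key(kg), trip_key(kg2))
  rp <- file.path(dir, "report.json")
  write_validation_report(validate_kg(kg), rp)
  expect_equal(jsonlite::read_json(rp)$n_errors, 0L)
})
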