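# Build a complete on-disk pipeline fixture (trait tables, classification
# report, metadata, tree) from the synthetic generator.
make_pipeline_fixture <- function(dir, n_a = 60, n_b = 80, seed = 1,
                                  with_tree = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- gen_trait_database(simulation_spec(n_taxa = c(n_a, n_b),
                                            seed = seed))
  paths <- list(db_a = file.path(dir, "skin.tsv"),
                db_b = file.path(dir, "world.tsv"),
                abundance = file.path(dir, "abund.tsv"),
                metadata = file.path(dir, "meta.tsv"))
  write_trait_table(sim$db_a, paths$db_a)
  write_trait_table(sim$db_b, paths$db_b)
  g <- gen_abundance_table(n_a, 12, abundant_fraction = 0.4, seed = seed)
  m <- g$table$values
  rownames(m) <- sim$db_a$data$species
  utils::write.table(
    data.frame(taxon = rownames(m), rank = "species", m,
               check.names = FALSE),
    paths$abundance, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = colnames(m), site = colnames(m),
               site_class = g$table$site_class),
    paths$metadata, sep = "\t", quote = FALSE, row.names = FALSE)
  if (with_tree) {
    paths$tree <- file.path(dir, "tree.nwk")
    tr <- gen_tree(n_a + n_b, seed = seed,
                   tip_labels = c(sim$db_a$data$species,
                                  sim$db_b$data$species))
    ape::write.tree(tr, paths$tree)
  }
  list(paths = paths, sim = sim, abundance_truth = g$truth)
}
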