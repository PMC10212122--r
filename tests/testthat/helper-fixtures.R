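# Tiny hand-built dataset used across tests: two quantified sites plus one
# qualitative site, a small taxonomy with nested ranks in both fish
# classes, and two period catch lists.

tiny_taxa <- function() {
  tibble::tribble(
    ~taxon_id, ~name, ~rank, ~lineage, ~fish_class,
    "class:Actinopterygii", "Actinopterygii", "class",
    "Actinopterygii", "bony",
    "class:Elasmobranchii", "Elasmobranchii", "class",
    "Elasmobranchii", "cartilaginous",
    "order:Siluriformes", "Siluriformes", "order",
    "Actinopterygii;Siluriformes", "bony",
    "family:Ariidae", "Ariidae", "family",
    "Actinopterygii;Siluriformes;Ariidae", "bony",
    "genus:Genidens", "Genidens", "genus",
    "Actinopterygii;Siluriformes;Ariidae;Genidens", "bony",
    "species:Genidens barbus", "Genidens barbus", "species",
    "Actinopterygii;Siluriformes;Ariidae;Genidens;Genidens barbus", "bony",
    "species:Bagre bagre", "Bagre bagre", "species",
    "Actinopterygii;Siluriformes;Ariidae;Bagre;Bagre bagre", "bony",
    "family:Sciaenidae", "Sciaenidae", "family",
    "Actinopterygii;Perciformes;Sciaenidae", "bony",
    "species:Micropogonias furnieri", "Micropogonias furnieri", "species",
    paste0("Actinopterygii;Perciformes;Sciaenidae;Micropogonias;",
      "Micropogonias furnieri"), "bony",
    "species:Carcharias taurus", "Carcharias taurus", "species",
    "Elasmobranchii;Lamniformes;Odontaspididae;Carcharias;Carcharias taurus",
    "cartilaginous",
    "genus:Sphyrna", "Sphyrna", "genus",
    "Elasmobranchii;Carcharhiniformes;Sphyrnidae;Sphyrna", "cartilaginous"
  )
}

tiny_sites <- function() {
  tibble::tibble(
    site_id = c("S1", "S2", "S3"),
    name = c("Site One", "Site Two", "Site Three"),
    latitude = c(-26.2, -28.0, -31.0),
    source_category = c("A", "A", "C"),
    mesh_mm = c(2, 5, NA),
    volume_m3 = c(2.0, 1.0, NA),
    median_age_cal_bp = c(3000, 1500, NA),
    quantification_basis = c("NISP", "NISP", "NISP")
  )
}

tiny_counts <- function() {
  tibble::tibble(
    site_id = c("S1", "S1", "S1", "S1", "S1", "S2", "S2", "S2"),
    cultural_phase = c(rep("Sambaqui", 5), rep("Sambaqui", 3)),
    taxon_id = c(
      "class:Actinopterygii", "species:Genidens barbus",
      "species:Micropogonias furnieri", "genus:Sphyrna",
      "class:Elasmobranchii",
      "species:Bagre bagre", "species:Carcharias taurus", "genus:Genidens"
    ),
    count = c(50, 25, 25, 10, 5, 10, 5, 3)
  )
}

tiny_traits <- function() {
  tibble::tibble(
    species = c(
      "Genidens barbus", "Bagre bagre", "Micropogonias furnieri",
      "Carcharias taurus", "Sphyrna lewini"
    ),
    trophic_level = c(3.6, 3.9, 3.4, 4.4, 4.1),
    trophic_group = c(
      "invertivore", "piscivore", "invertivore", "piscivore",
      "macrocarnivore"
    ),
    max_body_size_cm = c(120, 55, 60, 320, 430),
    max_body_mass_g = c(11000, 3200, 4600, 158900, 152400)
  )
}

tiny_periods <- function() {
  tibble::tibble(
    period_id = c("P1", "P1", "P1", "P2", "P2"),
    species = c(
      "Genidens barbus", "Micropogonias furnieri", "Bagre bagre",
      "Genidens barbus", "Carcharias taurus"
    )
  )
}

tiny_dataset <- function() {
  catch_dataset(
    tiny_taxa(), tiny_sites(), tiny_counts(), tiny_traits(), tiny_periods()
  )
}

write_tables <- function(dataset, dir = withr::local_tempdir(
                           .local_envir = parent.frame()
                         )) {
  write_dataset(dataset, dir)
  dir
}

read_back <- function(dir) {
  read_dataset(
    file.path(dir, "taxa.csv"), file.path(dir, "sites.csv"),
    file.path(dir, "counts.csv"), file.path(dir, "traits.csv"),
    file.path(dir, "periods.csv")
  )
}

small_sim_config <- function(seed = 42L, n_sites = 6L, ...) {
  generator_config(
    seed = seed,
    n_pool = 80L,
    n_species_per_period = c(P1 = 20L, P2 = 12L, P3 = 30L),
    n_sites = n_sites,
    total_nisp_range = c(200, 5000),
    ...
  )
}
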