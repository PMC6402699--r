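# Shared fixtures: the packaged registry, phenotype objects, and the
# published point values they must reproduce.

registry <- cosmo_registry()
phen <- registry_phenotypes(registry)

table1_values <- data.frame(
  strain = c(rep("1335", 6), rep("1340", 11)),
  parameter = c("b_max", "K", "n", "d", "c", "r",
                "b_max", "K", "n", "d", "c",
                "r_L(H=0)", "r_L(H=0.58)", "r_L(H=0.65)", "r_L(H=0.73)",
                "r_L(H=0.80)", "r_L(H=1.07)"),
  value = c(0.51, 2.1, 3.2, 0.0024, 5.4, 0.27,
            0.44, 1.3, 1.5, 0.015, 3.1,
            0.52, 0.83, 0.78, 0.53, 0.38, 0.08),
  lower = c(0.48, 1.7, 2.5, 0.0018, 5.1, 0.25,
            0.43, 1.2, 1.4, 0.014, 3.0,
            0.42, 0.70, 0.70, 0.45, 0.32, 0.05),
  upper = c(0.54, 2.4, 3.9, 0.0030, 5.7, 0.29,
            0.45, 1.4, 1.7, 0.016, 3.2,
            0.62, 0.96, 0.86, 0.61, 0.45, 0.11),
  stringsAsFactors = FALSE
)

# a simple symmetric phenotype pair for structural tests
symmetric_pair <- function(release = 0.5) {
  p <- strain_phenotype(moser_params(0.5, 2, 2), death = 0.01,
                        consumption = 4, release = release)
  list(LA = p, AL = p)
}
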