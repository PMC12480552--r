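# Simulate a two-treatment nested design: animals in treatments, planes
# within animals, two regions per plane (the replication the nested random
# intercepts need), on the log10(conc + 0.001) response scale.
simulate_nested <- function(seed, delta = 1, n_animals = c(A = 4, B = 3),
                            sd_animal = 0.2, sd_plane = 0.05, sd_res = 0.1,
                            n_planes = 5) {
  set.seed(seed)
  rows <- list()
  for (tr in names(n_animals)) {
    for (a in seq_len(n_animals[[tr]])) {
      re_a <- rnorm(1, 0, sd_animal)
      for (p in seq_len(n_planes)) {
        re_p <- rnorm(1, 0, sd_plane)
        for (r in c("parenchyma", "ventricle")) {
          mu <- 2 + (tr == "B") * delta + (r == "ventricle") * 0.5 +
            re_a + re_p
          rows[[length(rows) + 1]] <- tibble::tibble(
            animal_id = paste0(tr, a), plane = p, roi = r, treatment = tr,
            median = 10^(mu + rnorm(1, 0, sd_res)) - 0.001)
        }
      }
    }
  }
  section_observations(dplyr::bind_rows(rows))
}
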