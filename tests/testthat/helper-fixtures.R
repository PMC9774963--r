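# Fixture builders shared across test files.  Everything is constructed in
# code; no binary fixtures.

# a tiny deterministic 3-individual population with hand-picked values
tiny_population <- function() {
  t1 <- beak_trajectory("A", data.frame(index = 1:4,
                                        d13c = c(-20.5, -20.0, -19.5, -19.4),
                                        d15n = c(9.0, 10.0, 12.0, 13.0)),
                        sex = "female", mantle_length_mm = 210)
  t2 <- beak_trajectory("B", data.frame(index = 1:4,
                                        d13c = c(-20.4, -20.2, NA, -19.8),
                                        d15n = c(8.5, 9.5, 11.5, 12.5)),
                        sex = "male", mantle_length_mm = 230)
  t3 <- beak_trajectory("C", data.frame(index = 1:5,
                                        d13c = c(-20.0, -19.8, -19.2, -19.1, -19.3),
                                        d15n = c(9.5, 10.5, 12.5, 13.5, 13.2)),
                        sex = "female", mantle_length_mm = 250)
  beak_population(list(t1, t2, t3))
}

# printed by-sex range columns used in the published U tests
table1_sex_columns <- function() {
  tab <- table1_fixture()
  pick <- function(char, col, sex) {
    d <- tab[tab$character == char & tab$sex == sex, ]
    v <- d[[col]]
    v[!is.na(v)]
  }
  list(
    d13c_minmax_f = pick("d13c", "range_min_max", "female"),
    d13c_minmax_m = pick("d13c", "range_min_max", "male"),
    d13c_firstlast_f = pick("d13c", "range_first_last", "female"),
    d13c_firstlast_m = pick("d13c", "range_first_last", "male"),
    d15n_firstlast_f = pick("d15n", "range_first_last", "female"),
    d15n_firstlast_m = pick("d15n", "range_first_last", "male"))
}

# two well-separated synthetic sources for mixing tests
two_sources <- function() {
  rbind(source_spec("low", -20, 0.5, 5, 0.5),
        source_spec("high", -18, 0.5, 15, 0.5))
}
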