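# Shared fixtures: a down-scaled simulator configuration for fast tests
# (defaults remain the full study structure), and a tiny hand-built herd.

smallParams <- function(seed = 1, ...) {
  simParams(
    nYears = 2L,
    groups = list(
      list(name = 1L, nSires = 4L, nDams = 60L, damAges = 4:8),
      list(name = 2L, nSires = 4L, nDams = 60L, damAges = 4:8),
      list(name = 3L, nSires = 2L, nDams = 30L, damAges = 3L),
      list(name = 4L, nSires = 2L, nDams = 30L, damAges = 2L)),
    seed = seed, ...)
}

# three-generation toy herd: 2 founder dams, 2 bulls, 2 calves
toyHerd <- function() {
  HerdBook(
    data.frame(
      id = c("D1", "D2", "S1", "S2", "C1", "C2"),
      sex = c("F", "F", "M", "M", "F", "M"),
      birth_date = as.Date(c("2010-04-01", "2011-04-01", "2012-04-01",
                             "2012-05-01", "2015-04-05", "2015-04-20")),
      dam_id = c(NA, NA, NA, NA, "D1", "D2"),
      true_sire_id = c(NA, NA, NA, NA, "S1", "S2"),
      group = c(NA, NA, NA, NA, 1L, 1L),
      year = c(NA, NA, NA, NA, 2014L, 2014L),
      birth_weight = c(NA, NA, NA, NA, 38, 40),
      weaning_weight = c(NA, NA, NA, NA, 210, 220)),
    services = data.frame(sire_id = c("S1", "S2"), group = 1L,
                          year = 2014L))
}
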