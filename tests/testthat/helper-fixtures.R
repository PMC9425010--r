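# Shared synthetic fixtures, computed once per test run. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, make(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

dab_slide <- function() {
  fixture("dab_slide", function() {
    make_slide(n_nuclei = 20, stain_kind = "DAB", seed = 3)
  })
}

he_slide <- function() {
  fixture("he_slide", function() {
    make_slide(n_nuclei = 20, stain_kind = "HE", seed = 3)
  })
}

dab_features <- function() {
  fixture("dab_features", function() {
    s <- dab_slide()
    extract_nucleus_features(s$image, s$mask)
  })
}

small_cohort <- function() {
  fixture("small_cohort", function() make_cohort(n = 600, seed = 5))
}
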