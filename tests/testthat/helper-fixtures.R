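# shared helpers: effect tibbles and tiny study sets built in code

make_effects <- function(effect, se, ids = as.character(seq_along(effect))) {
  tibble::tibble(study_id = ids, effect = effect, se = se,
                 excluded = FALSE, reason = NA_character_)
}

make_contrast <- function(a, b, c, d, id = "s1") {
  tibble::tibble(study_id = id, model = "custom",
                 case_exposed = a, case_unexposed = b,
                 control_exposed = c, control_unexposed = d,
                 degenerate = (a == 0 & c == 0) | (b == 0 & d == 0))
}

# two-arm single-study set with given genotype counts
make_study <- function(case, ctrl, id = "s1") {
  tab <- table1_fixture()[0, ]
  tab[1, "study_id"] <- id
  tab[1, "disease"] <- "IBD"
  tab[1, "endpoints"] <- "myelotoxicity"
  tab[1, c("tt_case", "ct_case", "cc_case")] <- as.list(case)
  tab[1, c("tt_ctrl", "ct_ctrl", "cc_ctrl")] <- as.list(ctrl)
  tab
}
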