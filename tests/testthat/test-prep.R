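# Crystallization-agent rules, selenomethionine replacement, element
# assignment.

# polymer grid spans [3,9]^3 at spacing 3; helpers place hetero molecules
# relative to it
prep_fixture <- function() {
  bio <- polymer_grid()
  # GOL near the biomolecule (blacklist must override contacts)
  gol <- make_structure(sweep(ball_points(6, 1.5, 10), 2, c(6, 6, 11), "+"),
                        element = "C", resname = "GOL", chain = "X",
                        resid = 50L, hetero = TRUE)
  # 21-heavy-atom chain far away, no contacts
  big <- make_structure(cbind(50 + 1.5 * (1:21), 50, 50), element = "C",
                        resname = "LIG", chain = "X", resid = 51L,
                        hetero = TRUE)
  # small HEM far away
  hem <- make_structure(cbind(80 + 1.5 * (1:4), 80, 80), element = "C",
                        resname = "HEM", chain = "X", resid = 52L,
                        hetero = TRUE)
  # 4-heavy-atom molecule at cell centers of the grid: each atom ~2.6 A
  # from 8 grid atoms -> 32 contacts / 4 heavy = 8 > 2.5, none closer
  # than 1.9 A
  ctr <- make_structure(rbind(c(4.5, 4.5, 4.5), c(7.5, 4.5, 4.5),
                              c(4.5, 7.5, 4.5), c(4.5, 4.5, 7.5)),
                        element = "N", resname = "CTC", chain = "X",
                        resid = 53L, hetero = TRUE)
  # covalently attached single atom (1.5 A from a grid atom)
  cov <- make_structure(matrix(c(3, 3, 4.5), 1, 3), element = "O",
                        resname = "COV", chain = "X", resid = 54L,
                        hetero = TRUE)
  # small inert molecule: removed by default
  tiny <- make_structure(cbind(100 + 1.5 * (1:3), 100, 100), element = "C",
                         resname = "XYZ", chain = "X", resid = 55L,
                         hetero = TRUE)
  bind_structures(bio, gol, big, hem, ctr, cov, tiny)
}

test_that("ligand rules match their stated precedence", {
  st <- prep_fixture()
  v <- classify_hetero_molecules(st)
  verdict <- function(res) v[v$resname == res, ]
  expect_equal(verdict("GOL")$decision, "remove")
  expect_equal(verdict("GOL")$matched_rule, "blacklist-name")
  expect_equal(verdict("LIG")$decision, "keep")
  expect_equal(verdict("LIG")$matched_rule, "size")
  expect_equal(verdict("LIG")$n_heavy, 21L)
  expect_equal(verdict("HEM")$decision, "keep")
  expect_equal(verdict("HEM")$matched_rule, "heme-name")
  expect_equal(verdict("CTC")$decision, "keep")
  expect_equal(verdict("CTC")$matched_rule, "contacts")
  expect_equal(verdict("COV")$decision, "keep")
  expect_equal(verdict("COV")$matched_rule, "covalent")
  expect_equal(verdict("XYZ")$decision, "remove")
  expect_equal(verdict("XYZ")$matched_rule, "default-remove")
})

test_that("classification needs a polymer and is order-independent", {
  no_bio <- make_structure(matrix(rnorm(9), 3, 3), resname = "LIG",
                           hetero = TRUE)
  expect_error(classify_hetero_molecules(no_bio), "polymer")

  bio <- polymer_grid()
  a <- make_structure(cbind(50 + 1.5 * (1:21), 50, 50), resname = "AAA",
                      resid = 60L, hetero = TRUE)
  b <- make_structure(cbind(90 + 1.5 * (1:3), 90, 90), resname = "BBB",
                      resid = 61L, hetero = TRUE)
  v1 <- classify_hetero_molecules(bind_structures(bio, a, b))
  v2 <- classify_hetero_molecules(bind_structures(bio, b, a))
  key <- c(AAA = "keep", BBB = "remove")
  expect_equal(setNames(v1$decision, v1$resname)[names(key)], key)
  expect_equal(setNames(v2$decision, v2$resname)[names(key)], key)
  expect_equal(setNames(v1$matched_rule, v1$resname),
               setNames(v2$matched_rule, v2$resname)[names(
                 setNames(v1$matched_rule, v1$resname))])
})

test_that("ligand policies form a lattice in retained atoms", {
  st <- prep_fixture()
  keep_all <- apply_ligand_policy(st, "keep-all")
  default <- apply_ligand_policy(st, "default")
  remove_all <- apply_ligand_policy(st, "remove-all")
  expect_gte(n_atoms(keep_all), n_atoms(default))
  expect_gte(n_atoms(default), n_atoms(remove_all))
  # remove-all keeps exactly the polymer
  expect_equal(n_atoms(remove_all), sum(!st$atoms$hetero))
  # default keeps polymer + LIG + HEM + CTC + COV
  expect_setdiff <- setdiff(unique(default$atoms$resname),
                            c("GLY", "LIG", "HEM", "CTC", "COV"))
  expect_equal(expect_setdiff, character(0))
})

test_that("selenomethionine replacement renames residues and selenium", {
  xyz <- matrix(rnorm(24), 8, 3)
  atoms <- tibble::tibble(
    serial = 1:8,
    name = c("N", "CA", "SE", "CB", "N", "CA", "SE", "CB"),
    name_raw = c(" N  ", " CA ", "SE  ", " CB ", " N  ", " CA ", "SE  ",
                 " CB "),
    resname = "MSE", resid = rep(c(1L, 2L), each = 4), chain = "A",
    element = c("N", "C", "Se", "C", "N", "C", "Se", "C"),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], hetero = TRUE
  )
  st <- solvaxs:::.swx_structure_from_atoms(atoms, rep(c(1L, 2L), each = 4),
                                            NULL)
  out <- replace_selenomethionine(st)
  expect_equal(unique(out$atoms$resname), "MET")
  expect_equal(sum(out$atoms$element == "Se"), 0L)
  expect_equal(sum(out$atoms$element == "S"), 2L)
  expect_equal(out$atoms$name[c(3, 7)], c("SD", "SD"))
  expect_equal(n_atoms(out), 8L)
  expect_equal(coords(out), coords(st))
  # disabled toggle and no-MSE structures are identities
  expect_identical(replace_selenomethionine(st, enabled = FALSE), st)
  plain <- polymer_grid()
  expect_identical(replace_selenomethionine(plain), plain)
})

test_that("form-factor assignment keeps exotic ions and flags unknowns", {
  bio <- polymer_grid()
  zn <- make_structure(matrix(c(0, 0, 0), 1, 3), element = "Zn",
                       resname = "ZN", chain = "X", resid = 70L,
                       hetero = TRUE)
  wat <- make_structure(matrix(c(20, 20, 20, 20.8, 20, 20, 19.7, 20.6, 20),
                               3, 3, byrow = TRUE),
                        element = c("O", "H", "H"), resname = "HOH",
                        chain = "W", resid = 71L, hetero = TRUE)
  st <- bind_structures(bio, zn, wat)
  rep <- assign_form_factor_elements(st)
  expect_equal(rep$ff_key[rep$element == "Zn"], "Zn")
  expect_equal(rep$ff_key[rep$resname == "HOH"], c("OW", "HW", "HW"))
  expect_equal(unique(rep$ff_key[rep$resname == "GLY"]), "C")
  # unknown element: error names serial and residue
  bad <- st
  bad$atoms$element[1] <- "Qq"
  expect_error(assign_form_factor_elements(bad), "serial 1")
})
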