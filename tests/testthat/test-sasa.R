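test_that("isolated and buried atoms give the analytic extremes", {
  lone <- data.frame(element = "C", x = 0, y = 0, z = 0)
  r <- 1.70 + 1.4
  expect_equal(shrakeRupleySASA(lone), 4 * pi * r^2, tolerance = 1e-9)
  # cage of carbons on a sphere tight enough to occlude the center
  th <- seq(0, pi, length.out = 8)
  ph <- seq(0, 2 * pi, length.out = 16)[-16]
  g <- expand.grid(th = th, ph = ph)
  cage <- data.frame(element = "C",
                     x = 2.2 * sin(g$th) * cos(g$ph),
                     y = 2.2 * sin(g$th) * sin(g$ph),
                     z = 2.2 * cos(g$th))
  buried <- rbind(data.frame(element = "C", x = 0, y = 0, z = 0), cage)
  expect_equal(shrakeRupleySASA(buried)[1], 0)
})

test_that("relative accessibility is invariant to rigid motion and is
           normalized by the reference maxima", {
  prot <- buildTestProtein()
  acc <- relativeAccessibility(prot)
  expect_identical(nrow(acc), 2L)
  expect_true(all(acc$rel_access > 0))
  # near-isolated residues in this construction approach their maxima
  expect_true(all(acc$rel_access > 0.5))

  rot <- prot
  ang <- 0.7
  R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1), 3)
  xyz <- as.matrix(prot[, c("x", "y", "z")]) %*% R
  rot$x <- xyz[, 1] + 11; rot$y <- xyz[, 2] - 3; rot$z <- xyz[, 3] + 5
  acc2 <- relativeAccessibility(rot)
  expect_equal(acc2$rel_access, acc$rel_access, tolerance = 0.02)

  weird <- prot; weird$resname[1] <- "XXX"
  expect_error(relativeAccessibility(weird), "XXX")
})

test_that("exposure uses a strict threshold and consistent residue sets", {
  contacts <- data.frame(chain = "A", resno = 1:3, resname = "SER",
                         contacting = c(TRUE, FALSE, FALSE))
  acc <- data.frame(chain = "A", resno = 1:3, resname = "SER",
                    rel_access = c(0.5, 0.2, 0.21))
  ann <- classifyEnvironment(contacts, acc, exposureThreshold = 0.2)
  expect_identical(ann$exposed, c(TRUE, FALSE, TRUE))
  expect_true(ann$contacting[1])
  expect_error(classifyEnvironment(contacts, acc[1:2, ]), "differ")
})

test_that("annotateEnvironment flags rotameric residues and disulfides", {
  cys1 <- buildResidue("CYS", -65, origin = c(0, 0, 0), resno = 1L)
  cys2 <- buildResidue("CYS", -65, origin = c(40, 0, 0), resno = 2L)
  # place the second SG 2.0 A from the first to form a bridge
  sg1 <- as.numeric(cys1[cys1$atom == "SG", c("x", "y", "z")])
  cys2[cys2$atom == "SG", c("x", "y", "z")] <-
    as.list(sg1 + c(2.0, 0, 0))
  ser <- buildResidue("SER", 62, origin = c(80, 0, 0), resno = 3L)
  ala <- buildResidue("ALA", numeric(0), origin = c(120, 0, 0), resno = 4L)
  lat <- new("LatticeModel", atoms = rbind(cys1, cys2, ser, ala),
             spaceGroup = "P 1", cell = c(500, 500, 500, 90, 90, 90))
  ann <- annotateEnvironment(lat)
  expect_identical(ann$rotameric,
                   c(FALSE, FALSE, TRUE, FALSE))  # SS pair, SER, ALA
  annKeep <- annotateEnvironment(lat, excludeDisulfides = FALSE)
  expect_identical(annKeep$rotameric, c(TRUE, TRUE, TRUE, FALSE))
})
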