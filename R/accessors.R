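# Generics, accessors and show methods.

#' Grid shape of a voxelized object
#' @param x a [Phantom], [StructureSet] or [InfluenceMatrix].
#' @return integer vector of length 3.
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname gridShape
#' @export
setMethod("gridShape", "Phantom", function(x) x@gridShape)
#' @rdname gridShape
#' @export
setMethod("gridShape", "StructureSet", function(x) x@gridShape)
#' @rdname gridShape
#' @export
setMethod("gridShape", "InfluenceMatrix", function(x) x@gridShape)

#' Voxel spacing in mm
#' @param x a [Phantom].
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "Phantom", function(x) x@spacingMm)

#' Density array of a phantom
#' @param x a [Phantom].
#' @export
setGeneric("phantomDensity", function(x) standardGeneric("phantomDensity"))
#' @rdname phantomDensity
#' @export
setMethod("phantomDensity", "Phantom", function(x) x@density)

#' Structure roles present in a structure set
#' @param x a [StructureSet].
#' @export
setGeneric("structureRoles", function(x) standardGeneric("structureRoles"))
#' @rdname structureRoles
#' @export
setMethod("structureRoles", "StructureSet", function(x) names(x@masks))

#' Extract one structure mask
#' @param x a [StructureSet].
#' @param role structure role name, e.g. `"CTV_HIGH"`.
#' @return logical array, or `NULL` when the role is absent.
#' @export
setGeneric("structureMask", function(x, role) standardGeneric("structureMask"))
#' @rdname structureMask
#' @export
setMethod("structureMask", "StructureSet", function(x, role) x@masks[[role]])

#' Spot table and weights of a spot set or plan
#' @param x a [SpotSet] or [ProtonPlan].
#' @export
setGeneric("spotTable", function(x) standardGeneric("spotTable"))
#' @rdname spotTable
#' @export
setMethod("spotTable", "SpotSet", function(x) x@spots)
#' @rdname spotTable
#' @export
setMethod("spotTable", "ProtonPlan", function(x) x@spots@spots)

#' @rdname spotTable
#' @export
setGeneric("spotWeights", function(x) standardGeneric("spotWeights"))
#' @rdname spotTable
#' @export
setMethod("spotWeights", "SpotSet", function(x) x@weights)
#' @rdname spotTable
#' @export
setMethod("spotWeights", "ProtonPlan", function(x) x@spots@weights)

#' Replace spot weights
#' @param x a [SpotSet].
#' @param value non-negative numeric vector, one entry per spot.
#' @export
setGeneric("spotWeights<-", function(x, value) standardGeneric("spotWeights<-"))
#' @rdname spotWeights-set
#' @export
setMethod("spotWeights<-", "SpotSet", function(x, value) {
  x@weights <- value
  validObject(x)
  x
})

#' Dose array of an accumulated scenario
#' @param x an [AccumulatedDose].
#' @export
setGeneric("doseArray", function(x) standardGeneric("doseArray"))
#' @rdname doseArray
#' @export
setMethod("doseArray", "AccumulatedDose", function(x) x@dose)

#' Per-endpoint NTCP table of a scenario evaluation
#' @param x a [ScenarioNTCP].
#' @export
setGeneric("ntcpTable", function(x) standardGeneric("ntcpTable"))
#' @rdname ntcpTable
#' @export
setMethod("ntcpTable", "ScenarioNTCP", function(x) x@results)

#' Per-endpoint delta table of a report
#' @param x a [DeltaNTCPReport].
#' @export
setGeneric("deltaTable", function(x) standardGeneric("deltaTable"))
#' @rdname deltaTable
#' @export
setMethod("deltaTable", "DeltaNTCPReport", function(x) x@endpoints)

#' Any-of-four totals of a report
#' @param x a [DeltaNTCPReport].
#' @export
setGeneric("totalsTable", function(x) standardGeneric("totalsTable"))
#' @rdname totalsTable
#' @export
setMethod("totalsTable", "DeltaNTCPReport", function(x) x@totals)

setMethod("show", "Phantom", function(object) {
  cat(sprintf("Phantom: %s voxels @ %s mm\n",
              paste(object@gridShape, collapse = " x "),
              paste(format(object@spacingMm), collapse = " x ")))
  cat(sprintf("  density range [%.3g, %.3g]\n",
              min(object@density), max(object@density)))
})

setMethod("show", "StructureSet", function(object) {
  cat(sprintf("StructureSet with %d masks on a %s grid\n",
              length(object@masks), paste(object@gridShape, collapse = " x ")))
  v <- vapply(object@masks, sum, numeric(1))
  for (nm in names(v)) cat(sprintf("  %-20s %d voxels\n", nm, as.integer(v[nm])))
})

setMethod("show", "SpotSet", function(object) {
  cat(sprintf("SpotSet: %d spots over beam angles {%s} deg\n",
              nrow(object@spots),
              paste(sort(unique(object@spots$angleDeg)), collapse = ", ")))
  cat(sprintf("  total weight %.4g\n", sum(object@weights)))
})

setMethod("show", "ProtonPlan", function(object) {
  cat(sprintf("ProtonPlan: %d spots, setup robustness %.3g mm (%d scenarios)\n",
              nrow(object@spots@spots), object@robustness@setupUncertaintyMm,
              nrow(object@robustness@scenarioShifts)))
  cat(sprintf("  worst-case objective %.6g%s\n", object@objectiveValue,
              if (object@converged) "" else " (iteration cap reached)"))
})

setMethod("show", "AccumulatedDose", function(object) {
  cat(sprintf("AccumulatedDose [scenario %s]: %d fractions, max %.2f Gy(RBE)\n",
              object@label, nrow(object@fractionLog), max(object@dose)))
})

setMethod("show", "ScenarioNTCP", function(object) {
  cat(sprintf("ScenarioNTCP [%s]\n", object@label))
  r <- object@results
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %-28s %s\n", r$endpoint[i],
                if (r$evaluable[i]) sprintf("%6.2f %%", 100 * r$ntcp[i])
                else paste0("not evaluable (", r$reason[i], ")")))
})

setMethod("show", "DeltaNTCPReport", function(object) {
  cat(sprintf("DeltaNTCPReport [patient %s] (pp; negative = risk reduction)\n",
              object@patientId))
  e <- object@endpoints
  for (i in seq_len(nrow(e)))
    cat(sprintf("  %-28s SUR %+7.2f  AGC %+7.2f  SUR&AGC %+7.2f%s\n",
                e$endpoint[i], e$dSUR[i], e$dAGC[i], e$dBOTH[i],
                if (e$evaluable[i]) "" else "  [not evaluable]"))
  t4 <- object@totals
  i <- which(t4$quantity == "any_of_four")
  if (length(i))
    cat(sprintf("  any-of-four total            SUR %+7.2f  AGC %+7.2f  SUR&AGC %+7.2f\n",
                t4$dSUR[i], t4$dAGC[i], t4$dBOTH[i]))
})
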