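#' @rawNamespace exportClasses(DuplexSequence, HexamerRecord, HeptamerRecord,
#'   OligomerSet, ParameterSet, ShapeProfile, DuplexStiffness, DuplexModel,
#'   GlobalElasticRecord, PersistenceFit, CoordinateTimeSeries, HBondSeries,
#'   SurvivalFit)
#' @rawNamespace exportMethods(show, length)
NULL
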