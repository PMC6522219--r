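[{"cell_id":"cell01","n_frames":20000,"nucleus":{"before":[{"x":18,"y":10},{"x":17.7955549577344,"y":11.5529142706151},{"x":17.1961524227066,"y":13},{"x":16.2426406871193,"y":14.2426406871193},{"x":15,"y":15.1961524227066},{"x":13.5529142706151,"y":15.7955549577344},{"x":12,"y":16},{"x":10.4470857293849,"y":15.7955549577344},{"x":9,"y":15.1961524227066},{"x":7.75735931288072,"y":14.2426406871193},{"x":6.80384757729337,"y":13},{"x":6.20444504226559,"y":11.5529142706151},{"x":6,"y":10},{"x":6.20444504226559,"y":8.44708572938488},{"x":6.80384757729337,"y":7},{"x":7.75735931288071,"y":5.75735931288072},{"x":9,"y":4.80384757729337},{"x":10.4470857293849,"y":4.20444504226559},{"x":12,"y":4},{"x":13.5529142706151,"y":4.20444504226559},{"x":15,"y":4.80384757729337},{"x":16.2426406871193,"y":5.75735931288071},{"x":17.1961524227066,"y":7},{"x":17.7955549577344,"y":8.44708572938487}],"after":[{"x":18.8,"y":10.2},{"x":18.5955549577344,"y":11.7529142706151},{"x":17.9961524227066,"y":13.2},{"x":17.0426406871193,"y":14.4426406871193},{"x":15.8,"y":15.3961524227066},{"x":14.3529142706151,"y":15.9955549577344},{"x":12.8,"y":16.2},{"x":11.2470857293849,"y":15.9955549577344},{"x":9.8,"y":15.3961524227066},{"x":8.55735931288072,"y":14.4426406871193},{"x":7.60384757729337,"y":13.2},{"x":7.00444504226559,"y":11.7529142706151},{"x":6.8,"y":10.2},{"x":7.00444504226559,"y":8.64708572938488},{"x":7.60384757729337,"y":7.2},{"x":8.55735931288071,"y":5.95735931288072},{"x":9.8,"y":5.00384757729337},{"x":11.2470857293849,"y":4.40444504226559},{"x":12.8,"y":4.2},{"x":14.3529142706151,"y":4.40444504226559},{"x":15.8,"y":5.00384757729337},{"x":17.0426406871193,"y":5.95735931288071},{"x":17.9961524227066,"y":7.2},{"x":18.5955549577344,"y":8.64708572938487}]},"compartments":[{"before":[{"x":15.6,"y":9},{"x":15.4782072520181,"y":9.61229349178414},{"x":15.1313708498985,"y":10.1313708498985},{"x":14.6122934917841,"y":10.4782072520181},{"x":14,"y":10.6},{"x":13.3877065082159,"y":10.4782072520181},{"x":12.8686291501015,"y":10.1313708498985},{"x":12.5217927479819,"y":9.61229349178414},{"x":12.4,"y":9},{"x":12.5217927479819,"y":8.38770650821586},{"x":12.8686291501015,"y":7.86862915010152},{"x":13.3877065082159,"y":7.52179274798194},{"x":14,"y":7.4},{"x":14.6122934917841,"y":7.52179274798194},{"x":15.1313708498985,"y":7.86862915010152},{"x":15.4782072520181,"y":8.38770650821585}],"after":[{"x":16.4,"y":9.2},{"x":16.2782072520181,"y":9.81229349178414},{"x":15.9313708498985,"y":10.3313708498985},{"x":15.4122934917841,"y":10.6782072520181},{"x":14.8,"y":10.8},{"x":14.1877065082159,"y":10.6782072520181},{"x":13.6686291501015,"y":10.3313708498985},{"x":13.3217927479819,"y":9.81229349178414},{"x":13.2,"y":9.2},{"x":13.3217927479819,"y":8.58770650821586},{"x":13.6686291501015,"y":8.06862915010152},{"x":14.1877065082159,"y":7.72179274798194},{"x":14.8,"y":7.6},{"x":15.4122934917841,"y":7.72179274798194},{"x":15.9313708498985,"y":8.06862915010152},{"x":16.2782072520181,"y":8.58770650821585}]}],"nucleoli":[[{"x":10.2,"y":12},{"x":10.1086554390135,"y":12.4592201188381},{"x":9.84852813742386,"y":12.8485281374239},{"x":9.45922011883811,"y":13.1086554390135},{"x":9,"y":13.2},{"x":8.54077988116189,"y":13.1086554390135},{"x":8.15147186257614,"y":12.8485281374239},{"x":7.89134456098646,"y":12.4592201188381},{"x":7.8,"y":12},{"x":7.89134456098646,"y":11.5407798811619},{"x":8.15147186257614,"y":11.1514718625761},{"x":8.54077988116189,"y":10.8913445609865},{"x":9,"y":10.8},{"x":9.45922011883811,"y":10.8913445609865},{"x":9.84852813742386,"y":11.1514718625761},{"x":10.1086554390135,"y":11.5407798811619}]]}]
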