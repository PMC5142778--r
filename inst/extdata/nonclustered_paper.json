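{"nExcitatory":4000,"nInhibitory":1000,"tauM":{"E":15,"I":10},"biasRange":{"E":[1.1,1.2],"I":[1,1.05]},"vThreshold":1,"vReset":0,"refractory":5,"tauRise":1,"tauDecay":{"E":3,"I":2},"J":{"EE":0.024,"EI":-0.045,"IE":0.014,"II":-0.057},"p":{"EE":0.2,"EI":0.5,"IE":0.5,"II":0.5},"nClusters":0,"clusterSize":0,"pInEE":0.4854,"pOutEE":0.1942,"jInEE":0.0456,"jOutEE":0.024,"dt":0.05,"burnIn":2}
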