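# Kenya's eight former administrative provinces: land-border contiguity.
8
Nairobi Central
Nairobi Eastern
Nairobi RiftValley
Central Eastern
Central RiftValley
Coast Eastern
Coast NorthEastern
Coast RiftValley
Eastern NorthEastern
Eastern RiftValley
Nyanza RiftValley
Nyanza Western
RiftValley Western
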