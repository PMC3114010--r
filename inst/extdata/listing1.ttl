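@prefix ss:http://semanticscience.org/.
@prefix sio:http://semanticscience.org/resource/.
ss:Ethanol rdf:type sio:SIO_011125.
ss:Ethanol sio:SIO_000008 ss:EthanolSmilesDescriptor.
ss:EthanolSmilesDescriptor rdf:type sio:CHEMINF_000018; sio:SIO_000300 "OCC".
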