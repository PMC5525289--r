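>SIN1_SYNTHETIC synthetic stand-in constructed to the published Sin1 architecture statistics (not the UniProt B8CBQ8 record)
MKFSTAVFALLSASASGTAEDVNAASTGDAVSSTNQGSAEDTRRLQNNQQNQQNNCCCCC
CCCCCCNNQQNQNNQQCCCCCCCDEDEQNNQQNQQNNDEDEDEDEDEDNNQQNQNNQQED
EDEDEDEDEQNNQQNQQNNDEDEDEDEDEDNNQQNQNNQQEDEDEDEDEDKQNNQQNQQN
NKKKKKKKKKKKNNQQNQNNQQKKKKKKKKKKKQNNQQNQQNNKKKKKKKKGTANNQQNQ
NNQQSTGAVSTSGTAQNNQQNQQNNSTGAVSTSGTGGQKFALNNQQSTGAVSTSGTAQNN
QQNQQNNSTGAVSTSGTANNQQNQNNQQSTGAVSTSGTAQNNQQNQQNNSTGAVSTSGTA
NNQQNQNNQQSTGAVSTSGTAQNNQQILVAGFAIVGAIMFVAGIVAKSTGKDNSKSGHKS
TNEGSK
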