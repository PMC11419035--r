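>IGKV1-33 synthetic
EDPKAVRCCFIYCSNIDMLIDMHGNHAIWNKNNVASSIYFDVVFASPGPEWYCWSPPHQFSTVVNMHPMSFRFMSYAEKKYRELCNAYIYFLIYQGQPICNLWS
>IGKV1D-33 synthetic
EDPKAVRCCFIYCSNIDMLIDMHGNHAIWNKNNVASSIYFDVVFASPGPEWYCWSPPHQFSTVVNMHPMSFRFMSYAEKKYRELCNAYIYFLIYQGQPICNLWS
>IGKV1-39 synthetic
NYSLTIGFKPFKWVFTPMKWPKCQASMSLATIKAEGFLPIRLMYMTWHEDQQQCIKLERCIKKYCAHHEDKGDYETGTWIKEPCCTARDCPDAPDVNWFVPNRI
>IGKV1D-39 synthetic
NYSLTIGFKPFKWVFTPMKWPKCQASMSLATIKAEGFLPIRLMYMTWHEDQQQCIKLERCIKKYCAHHEDKGDYETGTWIKEPCCTARDCPDAPDVNWFVPNRI
>IGKV3-11 synthetic
SDGRATHRPGPQPNIHERHLNLWCVEFGYSLEELFLVNNADCKENPADWYIIITWLLGMNKGLQNCMHSNCRGSVQNHELASMRNWKHNTNAHDIWTPGKYTEA
>IGKV3-20 synthetic
WVRHNRGNISSIVHPICTHMTSMNDYQTAEIPIAWSRLCHKAMICIASEQGTNDGHPTEVVMKLPWFVNWMCNGKKYIPKYFTKREMTAETDRMICTMWGPVNT
>IGKV4-1 synthetic
SVAPAYGLDYPVKINSMFPMNESYENVGCEDGVEMALHKAWGQFRFQQMCQFVWHNWQTEFAWERNRVEANIAVNEMSWNRRSFWDECQHEGDANFPHIRHQFR
>IGLV1-36 synthetic
QMVQKPSIRFDPEKRSAQRYSFFVQIFKGMYSWPNVQLCCCKRILYAARIEWFWHLERHPNSKKDMDVFTPFCEWVGTRLTALYWDANVHWEPGTPKRESQYCY
>IGLV1-44 synthetic
TIMALSCKKFSMGINFNELMEPHDPPQGNFGGSDGHGLGHCKYFYLIFMRWYREVSKHCTVICHSGKSKPGPMMLLKSDSLGNIWDSNDSMITNCYEPWWEDVS
>IGLV2-14 synthetic
DAVMCHCANHTDHLLAKGPRQKNFVIWHGTWRYNKQLHHLQQDFYRMYWAVKGCFRMHINCVFPLPYIPWRYAHYWFHRSEIIPVNDIDRMVYKENLGVQRVAC
>IGLV3-1 synthetic
KFFQCIMIAEMQNQAMSHSQSISHRHQEECCFFLECETQRKQLYRHRYMSIKFKFMGEWKEEVPINELQICWCRCSHKPMCRDTPWNWWIKSTRWEWGGFAPFA
>IGLV6-57 synthetic
KLKPVTHQDMMTGTIDPSPDVELRDHCCCRFFLTKSPWFMADMHQWDYGGYTDEVASLLSPITMTAPEHPFPAYSAMGPHMPEIAHARKPAFLNERDLWFAHYL
>IGKJ1 synthetic
QATGVRYCFADISYNM
>IGKJ2 synthetic
DGGEDPEYIGSPRAVQ
>IGLJ2 synthetic
HEICVKPENTPWGRNK
>IGLJ3 synthetic
HEICVKPENTPWGRNK
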