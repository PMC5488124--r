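//%REPLACE %CL% =("CodeLibrary.mod") // Library to get code from, replace all
                                     // occurrences of %CL% with CodeLibrary.mod
//%REPLACE (%N%=("1","2"), %vol%=("0.05","0.05")) // Two compartments with volumes, replace
                      // all occurrences of %N% with 1,2 and %vol% with 0.05, 0.15
//%REPLACE (%AB%=("A","B","C") %PS3%=("6","5","4")) // 3 species, PS init values.
import nsrunit; unit conversion on; // Use cgs units for this model.
math example {                      // model declaration
// INDEPENDENT VARIABLES
//%GET %CL% odeDomains()     // Get odeDomains section from CodeLibrary.mod
//%INSERTSTART a2bParmsVars  // Specify params and vars section
// PARAMETERS
real Flow = 1 ml/(g*min);    // Flow rate
real PS%AB%12 = %PS3% ml/(g*min);   // Conductances: PSA12,PSB12,PSC12
real V%N% = %vol% ml/g;      // Volume of V1, V2
extern real %AB%in(t) mM;    // Inflowing concentrations
// DEPENDENT VARIABLES
real %AB%%N%(t) mM;          // A1,A2,B1,B2,C1,C2
// INITIAL CONDITIONS (IC's)
when(t=t.min)  %AB%%N%=0;    // Defines IC's for the ODEs
//%INSERTEND a2bParmsVars    // End params and var sec
//%INSERTSTART a2bCalc       // Specify calc section
// ODE CALCULATIONS
//%GET %CL% reactionCalc  ("A=A2","B=B2","V=V2","G=Ga2b")  // A->B reaction
//%GET %CL% MMreactionCalc ("A=B2","B=C2","V=V2","G=Gb2c", // B ->C MM reaction
//% "KmA=KmB2","VmaxA = VmaxB2", "KmA = KmB2")             // B ->C MM reaction continued
//%GET %CL% flowCalc ("Cin=%AB%in","C=%AB%1","V=V1","F=Flow","D=D%AB%1")
//%GET %CL% exchangeCalc ("C1=%AB%1","PS=PS%AB%12","C2=%AB%2")
//%COLLECT("%AB%%N%:t")      //Group all ODE calculations for a species together
//%INSERTEND a2bCalc }  // curly bracket ends model
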